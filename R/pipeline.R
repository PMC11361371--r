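#' Run the full quantification pipeline on one frame
#'
#' Composes the stages in order: mitochondrial mask (optional unsharp-mask
#' preprocessing, then thresholding) → foci segmentation per channel →
#' containment filtering against the network mask → shape descriptors →
#' overlap classification against the reference channel → category
#' summary → cell regions, phase calls and per-cell metrics → group
#' summaries. Every threshold and rule actually applied is recorded in the
#' run log, together with focus counts before and after filtering; output
#' CSVs embed the config hash and package version. Given the same inputs,
#' config and seed the outputs are byte-identical.
#'
#' Channel roles are taken from `config$channels`, a list mapping roles
#' (`mito`, `query_foci`, `reference_foci`, `dapi`, `edu`, `cyclinA`) to
#' channel names. `mito` and `query_foci` are required; without
#' `reference_foci` the colocalization stage is skipped with a logged
#' notice; without `dapi` the per-cell stage is skipped.
#'
#' @param config a [pipeline_config()] (fields: `input`, `channels`,
#'   `pixel_size`, `thresholds` with optional entries `mito`, `foci`,
#'   `nuclei`, `body` each `list(method=, threshold=)`, `unsharp`,
#'   `containment_rule`, `complete_tol`, `min_size`, `phase_thresholds`,
#'   `group_by`, `out_dir`).
#' @param frame optionally an in-memory [image_frame()] instead of reading
#'   `config$input`.
#' @return list (invisible) with `frame`, `mito_mask`, `foci` (named list
#'   of filtered foci sets), `per_focus`, `overlap_summary`, `cells`,
#'   `per_cell`, `group_summary`, `log` (character lines), `config_hash`.
#' @export
run_pipeline <- function(config, frame = NULL) {
  stopifnot(inherits(config, "pipeline_config") || is.list(config))
  log_lines <- character()
  log_add <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  hash <- config_hash(config)
  log_add("granulemap %s run, config=%s",
          as.character(utils::packageVersion("granulemap")), hash)

  frame_id <- "unknown"
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s | frame %s] %s", name, frame_id,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  frame <- stage("read", {
    if (is.null(frame)) {
      if (is.null(config$input)) stop("no input frame given")
      read_frame(config$input, config)
    } else frame
  })
  frame_id <- frame$id
  px <- frame$pixel_size
  roles <- config$channels
  if (is.null(roles$mito) || is.null(roles$query_foci)) {
    stop("config must map at least the 'mito' and 'query_foci' channel roles")
  }

  seg <- function(x, spec, min_size = config$min_size) {
    if (is.null(spec) || is.null(spec$method) || spec$method == "otsu") {
      segment_mask(x, px, method = "otsu", min_size = min_size)
    } else {
      segment_mask(x, px, method = "absolute", threshold = spec$threshold,
                   min_size = min_size)
    }
  }

  mito_mask <- stage("mito_mask", {
    m <- get_channel(frame, roles$mito)
    if (isTRUE(config$unsharp$enabled)) {
      m <- unsharp_mask(m, config$unsharp$radius, config$unsharp$weight)
      log_add("mito: unsharp mask radius=%g weight=%g",
              config$unsharp$radius, config$unsharp$weight)
    }
    mk <- seg(m, config$thresholds$mito)
    log_add("mito: method=%s threshold=%.6g area=%.6g um2",
            attr(mk, "method"), attr(mk, "threshold"), mask_area_um2(mk))
    mk
  })

  foci_roles <- c("query_foci", "reference_foci")
  foci_sets <- list()
  for (role in foci_roles) {
    ch <- roles[[role]]
    if (is.null(ch)) next
    foci_sets[[ch]] <- stage(paste0("segment_", role), {
      mk <- seg(get_channel(frame, ch), config$thresholds$foci)
      fk <- label_foci(mk, channel = ch)
      ff <- filter_by_mask(fk, mito_mask, rule = config$containment_rule)
      log_add("%s (%s): threshold=%.6g foci=%d, after %s containment filter=%d",
              ch, role, attr(mk, "threshold"), length(fk),
              config$containment_rule, length(ff))
      ff
    })
  }

  query_ch <- roles$query_foci
  per_focus <- stage("descriptors", shape_descriptors(foci_sets[[query_ch]]))

  overlap_summary <- NULL
  if (!is.null(roles$reference_foci)) {
    rec <- stage("overlap",
                 compute_overlap(foci_sets[[query_ch]],
                                 foci_sets[[roles$reference_foci]],
                                 complete_tol = config$complete_tol))
    per_focus <- merge(per_focus,
                       rec[, c("focus_id", "overlap_area_um2",
                               "overlap_pct", "category")],
                       by = "focus_id", sort = TRUE)
    if (nrow(rec)) {
      overlap_summary <- summarize_overlap(rec)
      log_add("overlap vs %s: none=%.2f%% partial=%.2f%% complete=%.2f%% (n=%d, complete_tol=%g)",
              roles$reference_foci, overlap_summary$pct_none,
              overlap_summary$pct_partial, overlap_summary$pct_complete,
              nrow(rec), config$complete_tol)
    }
  } else {
    log_add("no reference_foci role mapped: colocalization stage skipped")
  }
  per_focus <- cbind(frame = frame_id, per_focus)

  cells <- NULL
  per_cell <- NULL
  group_sum <- NULL
  if (!is.null(roles$dapi)) {
    cells <- stage("cells", {
      body <- if (!is.null(roles$cyclinA)) {
        bspec <- config$thresholds$body
        if (!is.null(bspec) && identical(bspec$method, "absolute")) {
          segment_mask(get_channel(frame, roles$cyclinA), px,
                       method = "absolute", threshold = bspec$threshold,
                       min_size = config$min_size)
        } else {
          segment_mask(get_channel(frame, roles$cyclinA), px,
                       min_size = config$min_size)
        }
      } else {
        mito_mask
      }
      nspec <- config$thresholds$nuclei
      nuc <- if (!is.null(nspec) && identical(nspec$method, "absolute")) {
        segment_mask(get_channel(frame, roles$dapi), px, method = "absolute",
                     threshold = nspec$threshold, min_size = 20L)
      } else {
        segment_mask(get_channel(frame, roles$dapi), px, min_size = 20L)
      }
      cs <- build_cell_regions(nuc, body, pixel_size = px)
      log_add("cells: %d nuclei seeded", n_cells(cs))
      cs
    })
    if (n_cells(cells) > 0L &&
        !is.null(roles$edu) && !is.null(roles$cyclinA)) {
      cells <- stage("phases", {
        thr <- config$phase_thresholds
        thr <- if (!is.null(thr)) {
          phase_thresholds(thr$edu_pos, thr$cyclinA_pos,
                           if (is.null(thr$dapi_min)) 0 else thr$dapi_min)
        } else NULL
        cs <- classify_phases(cells, get_channel(frame, roles$dapi),
                              get_channel(frame, roles$edu),
                              get_channel(frame, roles$cyclinA),
                              thresholds = thr)
        used <- attr(cs, "thresholds")
        log_add("phase thresholds: edu_pos=%.6g cyclinA_pos=%.6g dapi_min=%.6g",
                used$edu_pos, used$cyclinA_pos, used$dapi_min)
        cs
      })
    }
    if (n_cells(cells) > 0L) {
      per_cell <- stage("per_cell", {
        intensity_channels <- list()
        intensity_channels[[query_ch]] <- get_channel(frame, query_ch)
        pc <- cell_metrics(cells, mito_mask, foci_by_channel = foci_sets,
                           intensity_channels = intensity_channels)
        log_add("per-cell: %d cells, %d foci outside all cells",
                nrow(pc), attr(pc, "n_foci_unassigned"))
        cbind(frame = frame_id, pc)
      })
      group_sum <- stage("group_summary", {
        gb <- intersect(config$group_by, names(per_cell))
        if (length(gb)) group_summary(per_cell, gb) else NULL
      })
    }
  } else {
    log_add("no dapi role mapped: per-cell stage skipped")
  }

  out <- list(frame = frame, mito_mask = mito_mask, foci = foci_sets,
              per_focus = per_focus, overlap_summary = overlap_summary,
              cells = cells, per_cell = per_cell, group_summary = group_sum,
              log = log_lines, config_hash = hash)
  if (!is.null(config$out_dir)) {
    stage("write", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_table_csv(per_focus, file.path(config$out_dir, "per_focus.csv"),
                      hash)
      if (!is.null(overlap_summary)) {
        write_table_csv(cbind(frame = frame_id, overlap_summary),
                        file.path(config$out_dir, "overlap_summary.csv"), hash)
      }
      if (!is.null(per_cell)) {
        write_table_csv(per_cell, file.path(config$out_dir, "per_cell.csv"),
                        hash)
      }
      if (!is.null(group_sum)) {
        write_table_csv(group_sum,
                        file.path(config$out_dir, "group_summary.csv"), hash)
      }
      writeLines(c(log_lines, sprintf("finished %s",
                                      format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
                 file.path(config$out_dir, "run.log"))
    })
  }
  invisible(out)
}
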