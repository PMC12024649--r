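# Table readers/writers, configuration validation, and the pipeline driver.
# All tables are plain UTF-8 CSV with a header row and "." decimal.

#' Read a single-cell trace table
#'
#' Expects columns `cell_id`, `parent_id`, `time_h`, `length_um`,
#' `fluor_total` (additional columns are kept as-is but ignored). Rows are
#' grouped by cell and sorted by time. Dangling parent references are
#' reported as a warning but the records are still loaded.
#'
#' @param path CSV file path
#' @return named list of [cell_record()]
#' @export
read_trace_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "parent_id", "time_h", "length_um", "fluor_total")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trace table is missing column(s): ", paste(miss, collapse = ", "))
  d <- d[order(d$cell_id, d$time_h), ]
  ids <- unique(d$cell_id)
  cells <- list()
  for (id in ids) {
    rows <- d[d$cell_id == id, ]
    if (any(diff(rows$time_h) <= 0))
      stop("non-monotone times within cell ", id)
    pid <- rows$parent_id[1]
    if (is.null(pid) || is.na(pid) || pid == "") pid <- NA_character_
    cells[[as.character(id)]] <-
      cell_record(id, pid, rows$time_h, rows$length_um, rows$fluor_total)
  }
  for (id in names(cells)) {
    pid <- cells[[id]]$parent_id
    if (!is.na(pid) && !is.null(cells[[pid]]))
      cells[[pid]]$daughters <- unique(c(cells[[pid]]$daughters, id))
  }
  orphans <- vapply(cells, function(cl)
    !is.na(cl$parent_id) && is.null(cells[[cl$parent_id]]), NA)
  if (any(orphans)) {
    missing_parents <- unique(vapply(cells[orphans],
                                     function(cl) cl$parent_id, ""))
    warning("dangling parent_id(s) ",
            paste(missing_parents, collapse = ", "),
            " referenced by cell(s): ",
            paste(names(cells)[orphans], collapse = ", "))
  }
  cells
}

#' Write a single-cell trace table
#'
#' Inverse of [read_trace_table()].
#'
#' @param cells named list of [cell_record()]
#' @param path output CSV path
#' @export
write_trace_table <- function(cells, path) {
  rows <- lapply(cells, function(cl)
    data.frame(cell_id = cl$cell_id,
               parent_id = ifelse(is.na(cl$parent_id), "", cl$parent_id),
               time_h = cl$time, length_um = cl$length,
               fluor_total = cl$fluor))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read/write a long-format plate table
#'
#' Long CSV with columns `well`, `time_h`, `od600`, `signal` plus optional
#' metadata columns (constant within a well), one [plate_series()] per well.
#'
#' @param path CSV file path
#' @return named list of [plate_series()]
#' @export
read_plate_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_h", "od600", "signal")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("plate table is missing column(s): ", paste(miss, collapse = ", "))
  meta_cols <- setdiff(names(d), need)
  out <- list()
  for (wl in unique(d$well)) {
    rows <- d[d$well == wl, ]
    rows <- rows[order(rows$time_h), ]
    meta <- as.list(rows[1, meta_cols, drop = FALSE])
    out[[as.character(wl)]] <- plate_series(rows$time_h, rows$od600,
                                            rows$signal, meta)
  }
  out
}

#' @rdname read_plate_table
#' @param wells named list of [plate_series()]
#' @export
write_plate_table <- function(wells, path) {
  rows <- lapply(names(wells), function(wl) {
    s <- wells[[wl]]
    base <- data.frame(well = wl, time_h = s$time, od600 = s$od600,
                       signal = s$signal)
    for (nm in names(s$meta)) base[[nm]] <- s$meta[[nm]]
    base
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a critical curve or phase grid as tidy CSV
#'
#' @param x a `critical_curve` or `phase_grid`
#' @param path output CSV path
#' @export
write_phase_csv <- function(x, path) {
  d <- if (inherits(x, "phase_grid")) as.data.frame(x) else as.data.frame(x)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Fraction of induced cells after a burn-in
#'
#' Applies the monitoring filter (at least `min_frames` frames after the
#' burn-in), classifies each qualifying trace with [classify_trace()] on its
#' post-burn-in frames, discards mixed traces, and reports the induced
#' fraction with the bookkeeping counts.
#'
#' @param cells named list of [cell_record()]
#' @param burn_in discard frames before this time (h); 5 h by default, 14 h
#'   recommended near the coexistence region
#' @param threshold_molecules induced/uninduced threshold
#' @param min_frames monitoring filter (default 10 frames)
#' @return list with `fraction`, `n_induced`, `n_uninduced`, `n_mixed`,
#'   `n_filtered`
#' @export
induced_fraction <- function(cells, burn_in = 5, threshold_molecules = 250,
                             min_frames = 10) {
  n_ind <- n_unind <- n_mix <- n_filt <- 0L
  for (cl in cells) {
    keep <- cl$time >= burn_in & !is.na(cl$fluor)
    if (sum(cl$time >= burn_in) < min_frames || !any(keep)) {
      n_filt <- n_filt + 1L
      next
    }
    sub <- cell_record(cl$cell_id, cl$parent_id, cl$time[keep],
                       cl$length[keep], cl$fluor[keep])
    cls <- classify_trace(sub, threshold_molecules)
    if (cls == "induced") n_ind <- n_ind + 1L
    else if (cls == "uninduced") n_unind <- n_unind + 1L
    else n_mix <- n_mix + 1L
  }
  denom <- n_ind + n_unind
  list(fraction = if (denom > 0) n_ind / denom else NA_real_,
       n_induced = n_ind, n_uninduced = n_unind, n_mixed = n_mix,
       n_filtered = n_filt)
}

#' Detect switches along each mother-machine channel
#'
#' Concatenates the per-cell instantaneous estimates of each channel's
#' mother line in time order (regressions stay within cells, so divisions
#' do not produce rate spikes) and runs [detect_switches()] on the combined
#' trace.
#'
#' @param cells named list of [cell_record()] whose ids follow the
#'   generator's `chXX_cYYY` convention (sibling tracks `_sib` are ignored)
#' @param w,diameter,beta passed to [estimate_instantaneous()]
#' @param log_threshold switch threshold (natural log)
#' @return data.frame of events with a `channel` column
#' @export
channel_switches <- function(cells, w = 5, diameter = 0.9, beta = 0,
                             log_threshold = 5.5) {
  ids <- names(cells)
  ids <- ids[!grepl("_sib$", ids)]
  chans <- sub("^ch(\\d+)_.*$", "\\1", ids)
  out <- list()
  for (ch in unique(chans)) {
    sel <- ids[chans == ch]
    est <- lapply(sel, function(id) {
      cl <- cells[[id]]
      if (length(cl$time) < w) return(NULL)
      estimate_instantaneous(cl, w, diameter, beta)
    })
    est <- do.call(rbind, est[!vapply(est, is.null, NA)])
    if (is.null(est) || nrow(est) < 2) next
    est <- est[order(est$time), ]
    ev <- detect_switches(est, log_threshold)
    if (nrow(ev)) {
      ev$channel <- as.integer(ch)
      out[[length(out) + 1]] <- ev
    }
  }
  if (!length(out))
    return(cbind(empty_events(), data.frame(channel = integer(0))))
  do.call(rbind, out)
}

#' Validate and run a pipeline configuration
#'
#' A run configuration is a list with a `command`, a `seed`, an output
#' directory `out_dir`, and command-specific parameter blocks. Supported
#' commands: `"critical_curve"` (model preset + doubling-time axis),
#' `"fit_slope"` (threshold-point CSV in, slope JSON-ready list out) and
#' `"simulate_plate"`. Every artifact written is re-readable by the
#' package's own readers, and the returned summary carries the seed and the
#' per-stage bookkeeping counts.
#'
#' @param cfg configuration list
#' @return summary list (also written as CSV artifacts under `out_dir` when
#'   provided)
#' @export
run_pipeline <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$command))
  seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  res <- switch(cfg$command,
    critical_curve = {
      spec <- do.call(switch_preset, c(list(kind = cfg$model), cfg$params))
      cc <- critical_curve(spec, cfg$t_axis)
      if (!is.null(out_dir))
        write_phase_csv(cc, file.path(out_dir, "critical_curve.csv"))
      list(curve = cc, n_points = nrow(cc))
    },
    fit_slope = {
      pts <- utils::read.csv(cfg$points_csv)
      fit <- fit_loglog_slope(pts)
      list(a_mean = fit$a_mean, a_sd = fit$a_sd, sigma_hat = fit$sigma_hat)
    },
    simulate_plate = {
      gen <- gen_plate_dataset(do.call(plate_gen_config,
                                       c(cfg$plate, list(seed = seed))))
      if (!is.null(out_dir)) {
        names(gen$wells) <- sprintf("w%03d", seq_along(gen$wells))
        write_plate_table(gen$wells, file.path(out_dir, "plate.csv"))
        utils::write.csv(gen$truth, file.path(out_dir, "plate_truth.csv"),
                         row.names = FALSE)
      }
      list(n_wells = length(gen$wells))
    },
    stop("unknown command: ", cfg$command))
  c(list(command = cfg$command, seed = seed,
         package_version = as.character(utils::packageVersion("gcsens"))),
    res)
}

#' Serialize a switch model to JSON and back
#'
#' One JSON document per model, with a schema version; round-trips through
#' [read_model_json()].
#'
#' @param spec a `switch_model`
#' @param path output JSON path
#' @export
write_model_json <- function(spec, path) {
  stopifnot(inherits(spec, "switch_model"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for model serialization")
  doc <- list(schema = "gcsens-model/1", kind = spec$kind,
              modulation = spec$modulation, params = spec$params)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for model serialization")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema) || !startsWith(doc$schema, "gcsens-model/"))
    stop("not a gcsens model document: ", path)
  do.call(switch_preset,
          c(list(kind = doc$kind, modulation = doc$modulation), doc$params))
}
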