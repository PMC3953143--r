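#' Run the measurement pipeline from files to a report
#'
#' File-level front end to [estimate_loop_length()]: reads the skeleton (MRC
#' or text), the helix annotations, runs the pipeline, and writes the report.
#' Errors are signalled with distinct condition classes so a shell wrapper can
#' map them to exit codes: `looprule_input_error` (unreadable/invalid input),
#' `looprule_empty_skeleton` (nothing left after helix masking), and
#' `looprule_all_infeasible` (no endpoint pair admits a path).
#'
#' @param config Named list; recognised entries: `skeleton` (path),
#'   `skeleton_format` ("auto", "mrc", "text"), `threshold` (MRC density
#'   threshold), `permissive` (MRC axis normalisation), `helices` (path),
#'   `n_residues`, `mask_radius`, `mask_boundary`, `max_edge`, `edge_strict`,
#'   `attach_cutoff`, `epsilon`, `sweep` (c(min, max, step)), `weighted`,
#'   `report` (output path), `format` ("tsv" or "json"), `verbose`.
#' @return The `loop_length_fit`, invisibly.
#' @export
run_measurement <- function(config) {
  cfg <- run_config(config)
  fail_input <- function(msg) {
    stop(structure(class = c("looprule_input_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1L))))
  }
  if (is.null(cfg$skeleton) || !file.exists(cfg$skeleton)) {
    fail_input(sprintf("skeleton file '%s' not found", cfg$skeleton))
  }
  if (is.null(cfg$helices) || !file.exists(cfg$helices)) {
    fail_input(sprintf("helix annotation file '%s' not found", cfg$helices))
  }
  fmt <- cfg$skeleton_format
  if (fmt == "auto") {
    fmt <- if (grepl("\\.(mrc|map|ccp4)$", cfg$skeleton, ignore.case = TRUE))
      "mrc" else "text"
  }
  cloud <- tryCatch(
    if (fmt == "mrc") {
      read_skeleton_mrc(cfg$skeleton, threshold = cfg$threshold,
                        permissive = cfg$permissive)
    } else {
      read_skeleton_text(cfg$skeleton)
    },
    error = function(e) fail_input(conditionMessage(e)))
  helices <- tryCatch(read_helices(cfg$helices),
                      error = function(e) fail_input(conditionMessage(e)))
  if (cfg$verbose) {
    message(sprintf("skeleton: %d points (voxel %g A); %d helices",
                    nrow(cloud$points), cloud$voxel_size, length(helices)))
  }
  fit <- estimate_loop_length(cloud, helices, n_residues = cfg$n_residues,
                              mask_radius = cfg$mask_radius,
                              mask_boundary = cfg$mask_boundary,
                              max_edge = cfg$max_edge,
                              edge_strict = cfg$edge_strict,
                              attach_cutoff = cfg$attach_cutoff,
                              epsilon = cfg$epsilon, sweep = cfg$sweep,
                              weighted = cfg$weighted)
  if (cfg$verbose) {
    message(sprintf("%d LCGs after masking; feasible pairs: %s",
                    length(fit$lcgs),
                    paste(fit$reports$pair[fit$reports$feasible], collapse = ", ")))
    for (i in seq_len(nrow(fit$reports))) {
      r <- fit$reports[i, ]
      message(sprintf("  %s: LCG %s (h = %.3f A), hops %s, epsilon %s",
                      r$pair, r$lcg_id, r$hausdorff,
                      ifelse(is.na(r$n_before), "-", r$n_before - 1L),
                      ifelse(is.na(r$epsilon), "-", format(r$epsilon))))
    }
  }
  if (!any(fit$reports$feasible)) {
    if (!is.null(cfg$report)) write_report(fit$reports, cfg$report, format = cfg$format)
    stop(structure(class = c("looprule_all_infeasible", "error", "condition"),
                   list(message = "all four endpoint pairs are infeasible",
                        call = sys.call())))
  }
  if (!is.null(cfg$report)) write_report(fit$reports, cfg$report, format = cfg$format)
  invisible(fit)
}

# Fill a run configuration with defaults and validate it.
run_config <- function(config = list()) {
  defaults <- list(skeleton = NULL, skeleton_format = "auto", threshold = 0.0,
                   permissive = FALSE, helices = NULL, n_residues = NULL,
                   mask_radius = 2.3, mask_boundary = "inclusive",
                   max_edge = 2.0, edge_strict = TRUE, attach_cutoff = 5.0,
                   epsilon = NULL, sweep = c(0, 6, 0.05), weighted = FALSE,
                   report = NULL, format = "tsv", verbose = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop(structure(class = c("looprule_input_error", "error", "condition"),
                   list(message = paste("unknown config entries:",
                                        paste(unknown, collapse = ", ")),
                        call = sys.call())))
  }
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$mask_radius > 0, cfg$max_edge > 0, cfg$attach_cutoff > 0,
            length(cfg$sweep) == 3L, cfg$sweep[1L] <= cfg$sweep[2L],
            cfg$sweep[3L] > 0)
  cfg
}

#' Save or load a run configuration as JSON
#'
#' A saved configuration reproduces an identical run when passed back to
#' [run_measurement()].
#'
#' @param config Named list as accepted by [run_measurement()].
#' @param path JSON file.
#' @export
save_run_config <- function(config, path) {
  cfg <- run_config(config)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1L))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$sweep <- as.numeric(cfg$sweep)
  run_config(cfg)
}
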