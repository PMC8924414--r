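# Report tables and run manifests. All library values are full precision;
# rounding (half-up, 2 decimals) happens only here, at the reporting
# boundary.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Base-case cost-effectiveness report table
#'
#' One row per reported quantity (per-state and total discounted costs and
#' QALYs, incremental cost and QALYs, ICER), one column per arm, rounded
#' half-up to 2 decimals.
#'
#' @param comparison A [run_comparison()] / [run_scenario()] result.
#' @return A data frame with columns `quantity`, `pembrolizumab`,
#'   `chemotherapy`.
#' @export
cea_table <- function(comparison) {
  if (!inherits(comparison, "comparison_result"))
    stop_validation("`comparison` must be a comparison_result")
  a <- comparison$arms
  ce <- comparison$ce
  r2 <- function(x) round_half_up(x, 2)
  data.frame(
    quantity = c("cost_pfs_usd", "cost_pd_usd", "cost_total_usd",
                 "incremental_cost_usd", "qaly_pfs", "qaly_pd", "qaly_total",
                 "incremental_qalys", "icer_usd_per_qaly", "dominance"),
    pembrolizumab = c(r2(a$pembrolizumab$cost_pfs), r2(a$pembrolizumab$cost_pd),
                      r2(a$pembrolizumab$cost_total), r2(ce$delta_cost),
                      r2(a$pembrolizumab$qaly_pfs), r2(a$pembrolizumab$qaly_pd),
                      r2(a$pembrolizumab$qaly_total), r2(ce$delta_qaly),
                      if (is.na(ce$icer)) NA else r2(ce$icer), ce$dominance),
    chemotherapy = c(r2(a$chemotherapy$cost_pfs), r2(a$chemotherapy$cost_pd),
                     r2(a$chemotherapy$cost_total), NA,
                     r2(a$chemotherapy$qaly_pfs), r2(a$chemotherapy$qaly_pd),
                     r2(a$chemotherapy$qaly_total), NA, NA, NA),
    stringsAsFactors = FALSE)
}

#' Export a cohort trace as CSV
#'
#' @param trace A [build_trace()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "cohort_trace"))
    stop_validation("`trace` must be a cohort_trace")
  d <- as.data.frame(unclass(trace))
  d <- cbind(cycle = 0:(nrow(d) - 1L), d)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

manifest_entry <- function(command, args, outputs, seed = NULL) {
  list(manifest_id = sprintf("%s-%s", command,
                             format(Sys.time(), "%Y%m%dT%H%M%OS3")),
       command = command,
       args = args,
       seed = seed,
       tool = "markovcea",
       version = as.character(utils::packageVersion("markovcea")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs)
}

append_manifest <- function(entry, out_dir) {
  path <- file.path(out_dir, "manifest.jsonl")
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, null = "null"), con)
  invisible(path)
}

# atomic write: write to a temp file in the same directory, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  file.rename(tmp, path)
  ok <- TRUE
  invisible(path)
}
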