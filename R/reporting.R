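# Publication-style outputs: results table, trace and CEAC exports, run
# manifest.

fmt_cad <- function(x) formatC(round(x), format = "d", big.mark = " ")

#' Render cost-utility results as a table
#'
#' One row per arm per analysis, in the layout of a published cost-utility
#' results table: mean (SD) cost, mean (SD) QALYs, incremental cost and
#' QALYs, ICER (or "Dominant"/"Dominated"), and INMB with its 95% credible
#' interval. Incremental columns are filled on the comparator (standard)
#' row. Currency cells are rounded to whole Canadian dollars for display;
#' the returned data.frame keeps full-precision numeric columns alongside.
#'
#' @param results named list of `cua_result` objects (names label the
#'   analyses, e.g. "Base case").
#' @param path optional file path; `.md` writes a Markdown pipe table,
#'   `.csv` the numeric columns.
#' @return data.frame (invisibly if `path` is given).
#' @export
render_results_table <- function(results, path = NULL) {
  rows <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    for (k in seq_len(nrow(r$arms))) {
      a <- r$arms[k, ]
      inc <- a$arm == "standard"
      icer_cell <- if (!inc) "" else switch(r$icer_flag,
        ratio = fmt_cad(r$icer),
        dominant = "Dominant", dominated = "Dominated", undefined = "Undefined")
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = nm, arm = a$arm,
        cost = sprintf("%s (%s)", fmt_cad(a$cost_mean), fmt_cad(a$cost_sd)),
        qalys = sprintf("%.2f (%.2f)", a$qaly_mean, a$qaly_sd),
        incremental_cost = if (inc) sprintf("%s (%s)",
          fmt_cad(r$delta_cost_mean), fmt_cad(r$delta_cost_sd)) else "",
        incremental_qalys = if (inc) sprintf("%.2f (%.2f)",
          r$delta_qaly_mean, r$delta_qaly_sd) else "",
        icer = icer_cell,
        inmb = if (inc) sprintf("%s (%s to %s)", fmt_cad(r$inmb_mean),
          fmt_cad(r$inmb_cri_mean[1]), fmt_cad(r$inmb_cri_mean[2])) else "",
        cost_mean = a$cost_mean, cost_sd = a$cost_sd,
        qaly_mean = a$qaly_mean, qaly_sd = a$qaly_sd,
        delta_cost_mean = if (inc) r$delta_cost_mean else NA_real_,
        delta_qaly_mean = if (inc) r$delta_qaly_mean else NA_real_,
        icer_value = if (inc) r$icer else NA_real_,
        inmb_mean = if (inc) r$inmb_mean else NA_real_,
        inmb_cri_low = if (inc) r$inmb_cri[1] else NA_real_,
        inmb_cri_high = if (inc) r$inmb_cri[2] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame(
    analysis = character(0), arm = character(0), cost = character(0),
    qalys = character(0), incremental_cost = character(0),
    incremental_qalys = character(0), icer = character(0),
    inmb = character(0), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "md") {
      disp <- tab[, c("analysis", "arm", "cost", "qalys", "incremental_cost",
                      "incremental_qalys", "icer", "inmb"),
                  drop = FALSE]
      hdr <- c("Analysis", "Group", "Cost, mean (SD), $",
               "QALYs, mean (SD)", "Incr. cost, $", "Incr. QALYs",
               "ICER, $/QALY", "INMB, mean (95% CrI), $")
      lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
                 paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
                 apply(disp, 1, function(r)
                   paste0("| ", paste(r, collapse = " | "), " |")))
      writeLines(lines, path)
    } else {
      utils::write.csv(tab, path, row.names = FALSE)
    }
    return(invisible(tab))
  }
  tab
}

#' Export a Markov trace as CSV
#'
#' One row per cycle (including cycle 0), full numeric precision.
#'
#' @param trace `markov_trace` matrix.
#' @param path CSV file path.
#' @return the written data.frame, invisibly.
#' @export
export_trace <- function(trace, path) {
  df <- data.frame(cycle = seq_len(nrow(trace)) - 1L, unclass(trace)[, ])
  write_precise_csv(df, path)
}

#' Export a cost-effectiveness acceptability curve as CSV
#'
#' @param ceac data.frame with `lambda` and `probability`.
#' @param path CSV file path.
#' @return the written data.frame, invisibly.
#' @export
export_ceac <- function(ceac, path) {
  write_precise_csv(ceac, path)
}

# CSV with numerics at full double precision (lossless re-import)
write_precise_csv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(df)
}

#' Run manifest
#'
#' Captures everything needed to byte-reproduce a stochastic run: the
#' configuration, seeds, draw counts, schedule calibration factors and
#' sampling fallbacks, and the package version.
#'
#' @param config `krt_config`.
#' @param seed seed(s) used.
#' @param n_sims number of PSA draws.
#' @param schedules output of [calibrated_schedules()] (optional).
#' @param extra named list of additional entries (e.g. fallback counts).
#' @param path optional JSON output path.
#' @return list (invisibly if `path` given).
#' @export
run_manifest <- function(config, seed, n_sims, schedules = NULL,
                         extra = list(), path = NULL) {
  man <- list(
    package = "krtcua",
    version = as.character(utils::packageVersion("krtcua")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    n_sims = n_sims,
    config = unclass(config),
    calibration_factors = if (!is.null(schedules)) {
      lapply(schedules, function(s) s$calibration_factor)
    },
    extra = extra)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(man))
  }
  man
}
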