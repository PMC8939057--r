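#' Read a wide-format response CSV
#'
#' Reads one row per person with a mandatory \code{pid} column, item columns
#' holding the questionnaire categories (1..5 for five-category items), and
#' any remaining columns treated as person covariates. Responses are recoded
#' to the 0-based analysis scale. Rows with any missing item response are
#' dropped (complete-case contract) and the count is reported.
#'
#' @param path CSV path (comma-separated, UTF-8, header row).
#' @param subscale_map named character vector item -> subscale; its names
#'   define which columns are items.
#' @param categories number of response categories (default 5).
#' @return a \code{\link{response_matrix}}; the number of dropped rows is
#'   attached as attribute \code{n_dropped}.
#' @export
read_responses_csv <- function(path, subscale_map, categories = 5) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"pid" %in% names(df)) stop("a 'pid' column is required")
  if (anyDuplicated(df$pid))
    stop("duplicate person id(s): ",
         paste(utils::head(unique(df$pid[duplicated(df$pid)]), 5), collapse = ", "))
  items <- names(subscale_map)
  missing_cols <- setdiff(items, names(df))
  if (length(missing_cols))
    stop("unknown item column(s): ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(df[items])
  if (!is.numeric(X)) {
    suppressWarnings(storage.mode(X) <- "numeric")
  }
  bad <- which(!is.na(X) & (X < 1 | X > categories | X != round(X)),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("out-of-range response at row %d, item %s: %s",
                 bad[1, 1], items[bad[1, 2]], X[bad[1, , drop = FALSE]]))
  incomplete <- apply(X, 1, anyNA)
  if (any(incomplete))
    message(sum(incomplete), " incomplete row(s) dropped (complete-case contract)")
  X <- X[!incomplete, , drop = FALSE] - 1L
  covars <- setdiff(names(df), c("pid", items))
  pf <- if (length(covars)) df[!incomplete, covars, drop = FALSE] else NULL
  out <- response_matrix(X, subscale_map = subscale_map, person_factors = pf,
                         item_ids = items,
                         max_score = rep(categories - 1L, length(items)))
  attr(out, "n_dropped") <- sum(incomplete)
  out
}

#' Write a response matrix as CSV
#'
#' Inverse of \code{\link{read_responses_csv}}: responses are written back
#' on the original 1-based category scale with a \code{pid} column and the
#' person covariates.
#'
#' @param resp a \code{\link{response_matrix}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_responses_csv <- function(resp, path) {
  stopifnot(inherits(resp, "response_matrix"))
  df <- data.frame(pid = seq_len(nrow(resp$scores)),
                   resp$scores + 1L, check.names = FALSE)
  if (!is.null(resp$person_factors)) df <- cbind(df, resp$person_factors)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an analysis configuration from YAML
#'
#' Builds a \code{\link{shortening_config}} from a YAML file with keys
#' matching the constructor's arguments (plus an optional
#' \code{subscale_map} block used by \code{\link{read_responses_csv}}).
#'
#' @param path YAML path.
#' @return list with elements \code{config} (a
#'   \code{\link{shortening_config}}) and \code{subscale_map}.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  map <- if (!is.null(y$subscale_map)) unlist(y$subscale_map)
  y$subscale_map <- NULL
  cf <- y[intersect(names(y), names(formals(shortening_config)))]
  if (!is.null(cf$content_flags)) cf$content_flags <- unlist(cf$content_flags)
  list(config = do.call(shortening_config, cf), subscale_map = map)
}

# stable hash of a configuration for provenance lines in reports
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

#' Write analysis reports to an output directory
#'
#' Serializes a \code{\link{run_shortening}} trace (or a single
#' \code{fit_report}) as: a per-step summary CSV (one row per analysis:
#' analysis, item_res_mean, item_res_sd, person_res_mean, person_res_sd,
#' chisq, chisq_p, psi, unidim_pct, unidim_ci_low, unidim_ci_high), per-step
#' item-fit CSVs, DIF CSVs, the conversion table CSV (columns raw_mean,
#' metric, logit, rounded to 2 decimals), a JSON trace, and a plain-text run
#' log carrying the configuration hash.
#'
#' @param x a \code{shortening_trace} or \code{fit_report}.
#' @param outdir output directory (created if absent).
#' @return character vector of the files written, invisibly.
#' @export
write_reports <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  summary_cols <- c("analysis", "item_res_mean", "item_res_sd",
                    "person_res_mean", "person_res_sd", "chisq", "chisq_p",
                    "psi", "unidim_pct", "unidim_ci_low", "unidim_ci_high")
  if (inherits(x, "fit_report")) {
    emit(x$summary[summary_cols], "summary.csv")
    emit(x$items, paste0("item_fit_", gsub("\\W+", "_", x$label), ".csv"))
    return(invisible(files))
  }
  stopifnot(inherits(x, "shortening_trace"))
  reports <- c(lapply(x$steps, `[[`, "report"), list(x$testlet_report))
  emit(do.call(rbind, lapply(reports, function(r) r$summary[summary_cols])),
       "summary.csv")
  for (s in x$steps) {
    slug <- gsub("\\W+", "_", s$label)
    emit(s$report$items, paste0("item_fit_", slug, ".csv"))
    if (!is.null(s$dif)) emit(as.data.frame(s$dif), paste0("dif_", slug, ".csv"))
  }
  conv <- data.frame(raw_mean = round_half_away(x$conversion_table$raw_mean),
                     metric = round_half_away(x$conversion_table$metric),
                     logit = round_half_away(x$conversion_table$logit))
  emit(conv, "conversion_table.csv")
  trace <- list(
    roster_sizes = x$roster_sizes,
    final_items = x$final_items,
    steps = lapply(x$steps, function(s) list(
      label = s$label, roster = s$roster,
      removed = s$removed,
      branch = if (!is.null(s$branch))
        list(subscale = s$branch$subscale, options = s$branch$options,
             chisq = s$branch$chisq, winner = s$branch$winner),
      summary = s$report$summary)),
    latent = if (!is.null(x$latent_structure)) list(
      average_latent_correlation = x$latent_structure$average_latent_correlation,
      ecv = x$latent_structure$ecv,
      reliability = as.list(x$latent_structure$reliability)))
  p <- file.path(outdir, "trace.json")
  jsonlite::write_json(trace, p, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, p)
  log <- c(sprintf("run: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("config_hash: %s", config_hash(unclass(x$config))),
           sprintf("roster: %s", paste(x$roster_sizes, collapse = " -> ")),
           vapply(x$steps, function(s) {
             if (is.null(s$removed)) sprintf("%s: final roster", s$label)
             else sprintf("%s: removed %s", s$label,
                          paste(sprintf("%s [%s]", s$removed$item,
                                        s$removed$rationale), collapse = "; "))
           }, ""))
  p <- file.path(outdir, "run_log.txt")
  writeLines(log, p)
  files <- c(files, p)
  invisible(files)
}
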