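#' Read a numeric design table
#'
#' Reads a comma-separated table with a mandatory header row and strictly
#' numeric cells ('.' decimal separator; scientific notation accepted).
#' Malformed input is reported with its row and column.
#'
#' @param path file path.
#' @param response_column optional name of the column to split off as the
#'   response.
#' @return with `response_column`: a list with matrix `X` and vector `y`;
#'   otherwise the full numeric matrix.
#' @export
read_design <- function(path, response_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 comment.char = "#")
  if (ncol(df) < 1L || nrow(df) < 1L) stop("empty table: ", path)
  M <- matrix(NA_real_, nrow(df), ncol(df),
              dimnames = list(NULL, names(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad) || anyNA(df[[j]]))
      stop(sprintf("non-numeric or missing cell at row %d, column '%s'",
                   if (length(bad)) bad[1L] else which(is.na(df[[j]]))[1L],
                   names(df)[j]))
    M[, j] <- v
  }
  if (is.null(response_column)) return(M)
  if (!response_column %in% colnames(M))
    stop("response column '", response_column, "' not found")
  list(X = M[, colnames(M) != response_column, drop = FALSE],
       y = M[, response_column])
}

#' Write fitted coefficients
#'
#' Writes a CSV with one row per predictor (standardized- and
#' original-scale coefficients, penalty weight, active flag), preceded by
#' `#`-comment lines recording the method, tuning values, intercept,
#' objective and a Karush-Kuhn-Tucker verification summary.
#'
#' @param fit an `"lqsso_fit"` object.
#' @param path output file path.
#' @param kkt optional result of [kkt_check()] to summarize in the header.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(fit, path, kkt = NULL) {
  stopifnot(inherits(fit, "lqsso_fit"))
  hdr <- c(sprintf("# method: %s", fit$method),
           sprintf("# lambda: %.17g", fit$lambda),
           sprintf("# tau: %s", format(fit$tau)),
           sprintf("# gamma: %s", format(fit$gamma)),
           sprintf("# q: %g", fit$q),
           sprintf("# intercept: %.17g", fit$intercept),
           sprintf("# objective: %.17g", fit$objective),
           sprintf("# converged: %s", fit$converged),
           sprintf("# active_set: %s",
                   paste(fit$active_set, collapse = " ")))
  if (!is.null(kkt))
    hdr <- c(hdr, sprintf("# kkt_ok: %s (worst active %.3g, inactive %.3g)",
                          kkt$ok, kkt$worst_active, kkt$worst_inactive))
  df <- data.frame(predictor = seq_along(fit$beta),
                   beta_standardized = fit$beta,
                   beta_original = fit$beta_original,
                   weight = fit$weights,
                   active = fit$beta != 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write benchmark metrics
#'
#' Tidy CSV, one row per (model, n, sigma, method) cell.
#'
#' @param records data frame from [run_experiment()] (rows may be bound
#'   over scenarios).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
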