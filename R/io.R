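#' Read a delimited sample file
#'
#' Reads one sample of univariate or bivariate observations from a delimited
#' text file: one observation per row, 1 or 2 numeric columns, optional header
#' row. The delimiter (comma, tab, semicolon or whitespace) is sniffed from
#' the first non-empty line. Missing or non-numeric cells are an error that
#' names the offending row and column — silent dropping would change the
#' sample the test sees.
#'
#' @param path File path.
#' @param columns Optional column names or indices selecting the 1 or 2
#'   numeric columns to use (default: all columns in the file).
#' @return A numeric vector (1 column) or a 2-column numeric matrix, in file
#'   row order.
#' @export
read_sample <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  sep <- sniff_sep(lines[[1L]])
  fields <- strsplit(lines[[1L]], sep)[[1L]]
  header <- any(is.na(suppressWarnings(as.numeric(fields))))
  df <- utils::read.table(text = paste(lines, collapse = "\n"),
                          sep = if (sep == "[[:space:]]+") "" else sep,
                          header = header, colClasses = "character",
                          strip.white = TRUE)
  if (!is.null(columns)) df <- df[, columns, drop = FALSE]
  if (!ncol(df) %in% 1:2)
    stop("expected 1 or 2 numeric columns, found ", ncol(df))
  num <- suppressWarnings(
    vapply(df, as.numeric, numeric(nrow(df)), USE.NAMES = FALSE))
  num <- matrix(num, nrow = nrow(df))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("missing or non-numeric value at row ", bad[1L, 1L], ", column ",
         bad[1L, 2L], " of ", path)
  if (ncol(num) == 1L) drop(num) else num
}

sniff_sep <- function(line) {
  if (grepl(",", line)) ","
  else if (grepl("\t", line)) "\t"
  else if (grepl(";", line)) ";"
  else "[[:space:]]+"
}

#' Write a test or simulation report
#'
#' Serializes a result together with its configuration into an auditable
#' artifact: JSON for single test fits, CSV for simulation tables
#' (data frames). Every report carries the configuration echo, the seed and
#' the package version, so a run can be reproduced from its own report.
#'
#' @param result An `"alb_test"`, `"alb_perm"`, `"alb_baseline"`, list, or a
#'   data frame (written as CSV).
#' @param path Output path.
#' @param config Optional named list echoed into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, config = list()) {
  if (is.data.frame(result)) {
    utils::write.csv(result, path, row.names = FALSE)
    return(invisible(path))
  }
  payload <- if (inherits(result, "alb_test")) {
    list(alb = result$statistic, p_value = result$p.value,
         critical_value = result$critical_value,
         t_quantile = result$t_quantile,
         bandwidth = bandwidth_value(result), kernel = result$kernel,
         m = result$m, n = result$n, alpha = result$alpha,
         n_perms = result$n_perm, seed = result$seed,
         log_bf = result$log_bf, bound = result$bound)
  } else if (inherits(result, "alb_baseline")) {
    c(list(method = result$method, statistic = result$statistic,
           p_value = result$p_value), result$settings)
  } else {
    as.list(result)
  }
  payload$config <- config
  payload$version <- as.character(utils::packageVersion("albtest"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Bivariate sonar demo (metal vs rock)
#'
#' Runs the bivariate ALB test with the t3 product kernel and reflection
#' boundary correction on the first two variables of the UCI "Connectionist
#' Bench (Sonar, Mines vs. Rocks)" dataset (m = 111 metal returns, n = 97 rock
#' returns; energies are inherently in [0, 1]). The dataset is **not**
#' bundled: `file` must point to a local copy of `sonar.all-data`, or
#' `download = TRUE` must be given explicitly, in which case the file is
#' fetched from the UCI repository over the network.
#'
#' @param file Path to a local `sonar.all-data` (60 numeric columns plus a
#'   final M/R label column).
#' @param download Fetch the file from the UCI repository (requires network;
#'   never done implicitly).
#' @param n_perm Number of permutations.
#' @param seed Permutation seed.
#' @return An `"alb_test"` fit on variables 1-2.
#' @export
sonar_demo <- function(file = NULL, download = FALSE, n_perm = 10000L,
                       seed = 1L) {
  url <- paste0("https://archive.ics.uci.edu/ml/machine-learning-databases/",
                "undocumented/connectionist-bench/sonar/sonar.all-data")
  if (is.null(file)) {
    if (!download)
      stop("sonar data not available: supply 'file' or set download = TRUE ",
           "to fetch it from the UCI repository")
    file <- tempfile(fileext = ".csv")
    utils::download.file(url, file, quiet = TRUE)
  }
  raw <- utils::read.csv(file, header = FALSE)
  lab <- raw[[ncol(raw)]]
  v12 <- as.matrix(raw[, 1:2])
  x <- v12[lab == "M", , drop = FALSE]
  y <- v12[lab == "R", , drop = FALSE]
  alb_test(x, y, kernel = "t", df = 3, reflect = TRUE, n_perm = n_perm,
           seed = seed)
}
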