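# Plain-text I/O: delimited pair/matrix readers and structured writers.

sniff_delimiter <- function(path) {
  line <- ""
  con <- file(path, "r")
  on.exit(close(con))
  while (!nzchar(trimws(line))) {
    line <- readLines(con, n = 1)
    if (!length(line)) stop("empty file: ", path, call. = FALSE)
  }
  counts <- vapply(c("\t", ",", ";"), function(d)
    lengths(regmatches(line, gregexpr(d, line, fixed = TRUE))), integer(1))
  if (all(counts == 0)) " " else c("\t", ",", ";")[which.max(counts)]
}

#' Read a paired sample from a delimited text file
#'
#' The delimiter (tab, comma, semicolon or whitespace) is sniffed from the
#' first line unless given; a header line is auto-detected. The first two
#' numeric columns become `x` and `y`; rows with non-finite values are
#' dropped with a message.
#'
#' @param path Path to a TSV/CSV file with at least 2 numeric columns.
#' @param delimiter Optional explicit delimiter.
#' @return A [mic_pair()].
#' @export
read_pairs <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- delimiter %||% sniff_delimiter(path)
  first <- utils::read.table(path, sep = sep, nrows = 1,
                             stringsAsFactors = FALSE)
  header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  if (sum(num) < 2)
    stop("format error: need at least 2 numeric columns, found ", sum(num),
         call. = FALSE)
  cols <- df[which(num)[1:2]]
  ok <- is.finite(cols[[1]]) & is.finite(cols[[2]])
  if (any(!ok))
    message("dropped ", sum(!ok), " row(s) with non-finite values")
  if (sum(ok) < 2)
    stop("degenerate input: fewer than 2 usable rows after filtering",
         call. = FALSE)
  mic_pair(cols[[1]][ok], cols[[2]][ok])
}

#' Read a genes-by-samples expression matrix
#'
#' Expects gene ids in the first column and sample ids in the header row.
#' Rows sharing a gene id are averaged.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Optional explicit delimiter.
#' @return A numeric matrix with gene ids as row names and sample ids as
#'   column names.
#' @export
read_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- delimiter %||% sniff_delimiter(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  vals <- df[-1]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(vals)[which(bad)[1]]
    stop("format error: non-numeric cell(s) in column `", col, "`",
         call. = FALSE)
  }
  m <- as.matrix(vals)
  if (anyDuplicated(ids)) {
    m <- rowsum(m, group = ids, reorder = FALSE)
    cnt <- as.vector(table(factor(ids, levels = rownames(m))))
    m <- m / cnt
  } else {
    rownames(m) <- ids
  }
  if (any(!is.finite(m)))
    stop("format error: missing or non-finite values in the matrix",
         call. = FALSE)
  m
}

#' Write a result object with configuration provenance
#'
#' `mic_result` and `mic_clustering` objects (and arbitrary lists) are
#' written as JSON; data frames (experiment tables) as TSV with the
#' provenance serialized into `#`-prefixed comment lines.
#'
#' @param result The object to serialize.
#' @param path Output path.
#' @param format `"json"` or `"tsv"` (default chosen from the object type).
#' @param config Optional [search_config()] (or any list) recorded as
#'   provenance.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = NULL, config = NULL) {
  format <- format %||% if (is.data.frame(result)) "tsv" else "json"
  if (!format %in% c("json", "tsv"))
    stop("`format` must be \"json\" or \"tsv\"", call. = FALSE)
  prov <- if (!is.null(config)) unclass(config)
  if (format == "json") {
    payload <- if (inherits(result, "mic_result")) {
      list(score = result$score, method = result$method,
           n_x = result$n_x, n_y = result$n_y,
           x_cuts = result$x_partition$cuts,
           y_cuts = result$y_partition$cuts,
           orientation = result$orientation, norm_mode = result$norm_mode,
           mutual_information = result$mutual_information,
           n_equ = result$n_equ, n = result$n, alpha = result$alpha,
           chi2_threshold = result$chi2_threshold)
    } else if (inherits(result, "mic_clustering")) {
      unclass(result)
    } else {
      result
    }
    if (!is.null(prov)) payload$config <- prov
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(prov))
      writeLines(paste0("# config: ",
                        jsonlite::toJSON(prov, auto_unbox = TRUE,
                                         null = "null")), con)
    utils::write.table(result, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
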