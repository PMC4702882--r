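#' Extract the species id from protein identifiers
#'
#' Protein identifiers follow the `"speciesid.proteinid"` convention used in
#' orthology database member files; the species token is everything before the
#' first `"."`.
#'
#' @param ids Character vector of protein identifiers.
#' @return Character vector of species identifiers.
#' @examples
#' species_of(c("9606.ENSP001", "10090.Q9R0P9"))
#' @export
species_of <- function(ids) {
  out <- sub("\\..*$", "", ids)
  bad <- !grepl(".", ids, fixed = TRUE) | out == "" | out == ids
  if (any(bad)) {
    stop("protein id(s) without species prefix: ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  out
}

# base-36 encoding of a non-negative integer, zero-padded; used for compact
# OG identifiers.
to_base36 <- function(i, width = 4L) {
  digits <- c(0:9, LETTERS)
  vapply(i, function(x) {
    stopifnot(x >= 0)
    out <- character(0)
    repeat {
      out <- c(digits[(x %% 36L) + 1L], out)
      x <- x %/% 36L
      if (x == 0L) break
    }
    paste0(paste(rep("0", max(0L, width - length(out))), collapse = ""),
           paste(out, collapse = ""))
  }, character(1))
}

# Read a tab-separated file honouring '#' comment lines and UTF-8, without any
# quoting -- the dialect shared by all the package's table formats.
read_tsv_lines <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], numbers = which(keep))
}

write_tsv_lines <- function(lines, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header)) lines <- c(paste0("#", header), lines)
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Deterministic formatting for bit-scores in TSV output: up to 6 significant
# digits, no scientific notation, stable across write/read/write cycles.
format_score <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, digits = 15)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
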