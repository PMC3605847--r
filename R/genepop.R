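#' Read a Genepop file
#'
#' Parses the classical Genepop text dialect: a title line, locus names (one
#' per line or comma-separated on one line), `POP` separators, then one line
#' per individual of the form `id ,  aabb aabb ...` with 2- or 3-digit allele
#' encoding and `00`/`000` as the missing code. A genotype with one missing
#' allele is treated as fully missing.
#'
#' Subpopulations are labelled in order of appearance. Following common
#' Genepop usage the label is taken from the id of the block's last
#' individual: its prefix before the first underscore/dash/dot if one exists,
#' otherwise blocks are named `P1...Pn`.
#'
#' @param path path to a Genepop file.
#' @param repeat_unit repeat-unit length per locus for downstream M-ratio use.
#' @return A [genotype_dataset()].
#' @export
read_genepop <- function(path, repeat_unit = 2L) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  if (length(lines) < 3L) stop("not a Genepop file: fewer than 3 lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no POP separator found")
  if (first_pop < 3L) stop("line ", first_pop, ": POP before any locus name")
  loci_lines <- trimws(lines[2:(first_pop - 1L)])
  loci_lines <- loci_lines[nzchar(loci_lines)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names found before first POP")

  pop_id <- cumsum(is_pop)
  body <- which(pop_id > 0L & !is_pop & nzchar(trimws(lines)))
  if (!length(body)) stop("no individual records found")

  n <- length(body)
  L <- length(loci)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  ids <- character(n)
  block <- integer(n)
  for (r in seq_len(n)) {
    ln <- body[r]
    txt <- lines[ln]
    parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("line ", ln, ": expected 'id , genotypes' (no comma found)")
    ids[r] <- trimws(parts[1])
    block[r] <- pop_id[ln]
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop("line ", ln, ": ", length(toks), " genotypes for ", L, " loci")
    w <- nchar(toks)
    if (any(w != w[1]) || !w[1] %in% c(4L, 6L))
      stop("line ", ln, ": genotype tokens must all be 4 (2-digit) or 6 ",
           "(3-digit) characters wide")
    if (any(grepl("[^0-9]", toks)))
      stop("line ", ln, ": non-numeric genotype token")
    d <- w[1] %/% 2L
    x1 <- as.integer(substr(toks, 1L, d))
    x2 <- as.integer(substr(toks, d + 1L, 2L * d))
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[r, ] <- x1; a2[r, ] <- x2
  }

  labels <- vapply(seq_len(max(block)), function(b) {
    last_id <- ids[max(which(block == b))]
    pre <- sub("^([^_.-]+)[_.-].*$", "\\1", last_id)
    if (nzchar(pre) && pre != last_id) pre else paste0("P", b)
  }, character(1))
  if (anyDuplicated(labels)) labels <- paste0("P", seq_along(labels))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "#")
  genotype_dataset(pop = factor(labels[block], levels = unique(labels[block])),
                   id = ids, a1 = a1, a2 = a2, loci = loci,
                   repeat_unit = repeat_unit)
}

#' Write a Genepop file
#'
#' @param ds a [genotype_dataset()].
#' @param path output path.
#' @param title title line (first line of the file).
#' @param digits allele-code width, 2 or 3; codes must fit (`<= 99` / `<= 999`).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(ds, path, title = "riverNe export", digits = 3L) {
  stopifnot(inherits(ds, "genotype_dataset"), digits %in% c(2L, 3L))
  mx <- suppressWarnings(max(ds$a2, na.rm = TRUE))
  if (is.finite(mx) && mx > 10^digits - 1)
    stop("allele codes exceed ", digits, "-digit encoding")
  fmt <- paste0("%0", digits, "d")
  enc <- function(x) {
    out <- sprintf(fmt, ifelse(is.na(x), 0L, x))
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(ds$loci, con)
  for (p in levels(ds$pop)) {
    writeLines("POP", con)
    idx <- which(ds$pop == p)
    for (i in idx) {
      g <- paste0(enc(ds$a1[i, ]), enc(ds$a2[i, ]))
      writeLines(paste0(ds$id[i], " ,  ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a delimited genotype table
#'
#' Convenience dialect equivalent to Genepop: one row per individual with
#' columns `pop`, `id`, then one column per locus holding `a1/a2` (e.g.
#' `102/104`), with `0/0`, `NA` or empty for missing.
#'
#' @param path path to a delimited text file with header.
#' @param sep field separator (default tab).
#' @param repeat_unit repeat-unit length per locus.
#' @return A [genotype_dataset()].
#' @export
read_genotype_table <- function(path, sep = "\t", repeat_unit = 2L) {
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 3L || !all(c("pop", "id") %in% names(df)[1:2]))
    stop("genotype table needs columns 'pop', 'id', then one per locus")
  loci <- names(df)[-(1:2)]
  split2 <- function(col) {
    parts <- strsplit(as.character(col), "/", fixed = TRUE)
    bad <- lengths(parts) != 2L & !is.na(col) & nzchar(as.character(col))
    if (any(bad))
      stop("malformed genotype (expected 'a1/a2') in rows: ",
           paste(head(which(bad)), collapse = ", "))
    x1 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) == 2L) p[1] else NA_character_, character(1))))
    x2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) == 2L) p[2] else NA_character_, character(1))))
    list(x1, x2)
  }
  cols <- lapply(df[loci], split2)
  a1 <- do.call(cbind, lapply(cols, `[[`, 1))
  a2 <- do.call(cbind, lapply(cols, `[[`, 2))
  a1[a1 <= 0L] <- NA_integer_; a2[a2 <= 0L] <- NA_integer_
  genotype_dataset(pop = df$pop, id = df$id, a1 = a1, a2 = a2, loci = loci,
                   repeat_unit = repeat_unit)
}

#' Write a delimited genotype table
#'
#' Inverse of [read_genotype_table()].
#' @inheritParams write_genepop
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ds, path, sep = "\t") {
  stopifnot(inherits(ds, "genotype_dataset"))
  geno <- matrix("0/0", length(ds$id), length(ds$loci),
                 dimnames = list(NULL, ds$loci))
  ok <- !is.na(ds$a1)
  geno[ok] <- paste0(ds$a1[ok], "/", ds$a2[ok])
  df <- data.frame(pop = as.character(ds$pop), id = ds$id, geno,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
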