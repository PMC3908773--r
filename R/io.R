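# Sequence readers, benchmark fixtures, the amino-acid -> HP encoder, and
# structure/report writers.

#' Read HP sequences from a file
#'
#' Reads either plain text (one H/P sequence per line, optionally
#' `name<TAB>sequence`) or FASTA records whose sequence lines are over the
#' HP alphabet (parsed with Biostrings).  Amino-acid FASTA input can be
#' converted on the fly via `hpEncode = TRUE`.
#'
#' @param path input file.
#' @param format `"auto"` (FASTA when the first non-blank character is
#'   `>`), `"text"` or `"fasta"`.
#' @param hpEncode convert amino-acid sequences with [hpEncode()] first.
#' @param ... passed to [hpEncode()].
#' @return A named character vector of HP sequences.
#' @export
readHPSequences <- function(path, format = c("auto", "text", "fasta"),
                            hpEncode = FALSE, ...) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) && startsWith(trimws(first), ">"))
      "fasta" else "text"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(set))
    names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  } else {
    ln <- trimws(readLines(path))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    parts <- strsplit(ln, "\t", fixed = TRUE)
    seqs <- toupper(vapply(parts, function(x) x[[length(x)]], ""))
    names(seqs) <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1L) parts[[i]][[1L]]
      else sprintf("seq%d", i), "")
  }
  if (hpEncode) seqs <- vapply(seqs, FCCfold::hpEncode, "", ...)
  for (s in seqs) .asHP(s)  # validate
  seqs
}

#' Benchmark HP sequence collections
#'
#' The four classical benchmark sets shipped with the package: data set I
#' (eight sequences of 20--64 residues), data set II (ten 48-residue
#' sequences), data set III (fifteen sequences of 90--200 residues), and
#' data set IV (five HP transforms of PDB protein sequences; their
#' amino-acid originals are available via [aaBenchmarks()]).  Where the
#' optimal (native) contact count is known it is given in
#' `referenceContacts`; unknown optima are `NA`.
#'
#' @param dataset `"I"`, `"II"`, `"III"` or `"IV"`.
#' @return A data frame with columns `dataset`, `name`, `length`,
#'   `sequence`, `referenceContacts`.
#' @examples
#' loadBenchmarks("I")[1, ]
#' @export
loadBenchmarks <- function(dataset = c("I", "II", "III", "IV")) {
  dataset <- match.arg(as.character(dataset), c("I", "II", "III", "IV"))
  path <- system.file("extdata", "benchmarks.tsv", package = "FCCfold",
                      mustWork = TRUE)
  all <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "character", "integer"))
  names(all) <- c("dataset", "name", "length", "sequence",
                  "referenceContacts")
  out <- all[all$dataset == dataset, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname loadBenchmarks
#' @export
aaBenchmarks <- function() {
  path <- system.file("extdata", "aa_benchmarks.tsv", package = "FCCfold",
                      mustWork = TRUE)
  out <- read.delim(path, stringsAsFactors = FALSE)
  names(out) <- c("name", "length", "aaSequence", "printedHP")
  out
}

#' Map an amino-acid sequence to the HP alphabet
#'
#' Residues in the hydrophobic set become H, all others P.  The default
#' set \{C, F, I, L, M, V, W\} reproduces the shipped benchmark HP
#' transforms on all spot-checked positions; it is configurable because no
#' single canonical hydrophobicity partition exists.
#'
#' @param aa amino-acid sequence (one-letter codes).
#' @param hydrophobic character vector of residue letters mapped to H.
#' @param unknown `"error"` (default) to reject letters outside the 20
#'   standard codes, or `"P"` to pass them through as polar.
#' @return An HP sequence string.
#' @examples
#' hpEncode("ALWQFNGMIK")   # "PHHPHPPHHP"
#' @export
hpEncode <- function(aa, hydrophobic = c("C", "F", "I", "L", "M", "V", "W"),
                     unknown = c("error", "P")) {
  unknown <- match.arg(unknown)
  if (length(aa) != 1L || is.na(aa)) stop("need a single sequence string")
  res <- strsplit(toupper(aa), "", fixed = TRUE)[[1L]]
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, std)
  if (length(bad) && unknown == "error")
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  paste(ifelse(res %in% toupper(hydrophobic), "H", "P"), collapse = "")
}

#' Label strings
#'
#' `labelString()` formats a conformation's direction labels as a
#' comma-separated string; `parseLabelString()` is its inverse and accepts
#' comma-, space- or dash-separated labels.
#'
#' @param conf a [Conformation-class].
#' @return `labelString()` a character scalar; `parseLabelString()` a
#'   [Conformation-class].
#' @examples
#' labelString(Conformation(c(1, 1, 6, 4)))
#' parseLabelString("1,1,6,4")
#' @export
labelString <- function(conf) {
  stopifnot(is(conf, "Conformation"))
  paste(conf@labels, collapse = ",")
}

#' @rdname labelString
#' @param x a label string.
#' @export
parseLabelString <- function(x) {
  parts <- strsplit(trimws(x), "[,;[:space:]-]+")[[1L]]
  parts <- parts[nzchar(parts)]
  Conformation(as.integer(parts))
}

#' Write a conformation
#'
#' `writeConformationTSV()` writes residue index, H/P class and integer
#' coordinates as tab-separated text.  `writeConformationXYZ()` writes an
#' xyz-style CA trace (one pseudo-atom per residue, element C for H and N
#' for P) readable by standard molecular viewers.
#'
#' @param s HP sequence string.
#' @param conf a [Conformation-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeConformationTSV <- function(s, conf, path) {
  isH <- .asHP(s)
  stopifnot(is(conf, "Conformation"), length(isH) == length(conf))
  df <- data.frame(residue = seq_len(length(conf)),
                   type = ifelse(isH, "H", "P"),
                   x = conf@coords[, 1L], y = conf@coords[, 2L],
                   z = conf@coords[, 3L])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConformationTSV
#' @export
writeConformationXYZ <- function(s, conf, path) {
  isH <- .asHP(s)
  stopifnot(is(conf, "Conformation"), length(isH) == length(conf))
  lines <- c(sprintf("%d", length(conf)),
             "HP chain CA trace on the FCC lattice (C = H, N = P)",
             sprintf("%s %.3f %.3f %.3f", ifelse(isH, "C", "N"),
                     conf@coords[, 1L], conf@coords[, 2L],
                     conf@coords[, 3L]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a fold report as JSON
#'
#' Serializes a [FoldResult-class] (sequence, configuration echo, seed,
#' best and mean contact counts, best label string and coordinates) to
#' JSON.
#'
#' @param result a [FoldResult-class].
#' @param path output file, or `NULL` to return the JSON string.
#' @return The path (invisibly), or the JSON string when `path` is NULL.
#' @export
writeFoldReport <- function(result, path = NULL) {
  stopifnot(is(result, "FoldResult"))
  cfg <- result@config
  rep <- list(
    sequence = result@sequence,
    n = nchar(result@sequence),
    config = list(populationSize = cfg@populationSize,
                  crossoverRate = cfg@crossoverRate,
                  mutationRate = cfg@mutationRate,
                  iterations = cfg@iterations, K = cfg@K,
                  gpmAttempts = cfg@gpmAttempts,
                  restarts = cfg@restarts),
    seed = result@seed,
    bestContacts = result@bestContacts,
    bestEnergy = -result@bestContacts,
    restartBests = result@restartBests,
    meanContacts = mean(result@restartBests),
    bestLabels = labelString(result@best),
    bestCoordinates = unname(apply(coordinates(result@best), 1L,
                                   paste, collapse = " ")))
  json <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
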