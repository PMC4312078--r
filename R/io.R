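# FASTA / Newick / TSV / JSON readers and writers shared by all stages.

IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "-")

#' Read a (multi-)FASTA file into a tibble
#'
#' Record ids are taken up to the first whitespace, sequences are uppercased
#' and `U` is converted to `T`. Records containing characters outside the
#' IUPAC nucleotide alphabet, duplicated ids, or an empty file raise errors
#' naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 a marker", "acgt", ">s2", "GGTTAA"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) {
    stop("FASTA file is empty: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate FASTA record id: '", dup, "' in ", path, call. = FALSE)
  }
  seqs <- chartr("U", "T", toupper(as.character(recs)))
  bad <- vapply(
    strsplit(seqs, "", fixed = TRUE),
    function(ch) any(!ch %in% IUPAC_DNA),
    logical(1)
  )
  if (any(bad)) {
    stop("non-IUPAC characters in FASTA record '", ids[which(bad)[1]],
         "' in ", path, call. = FALSE)
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with an id column (first) and a `sequence` column, or a
#'   named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.character(x) && !is.null(names(x))) {
    x <- tibble::tibble(id = names(x), sequence = unname(x))
  }
  stopifnot(is.data.frame(x), "sequence" %in% names(x))
  ids <- as.character(x[[1]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    seq <- x$sequence[i]
    chunks <- substring(seq, seq(1, nchar(seq), width),
                        pmin(seq(1, nchar(seq), width) + width - 1, nchar(seq)))
    writeLines(c(paste0(">", ids[i]), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Serialize a phylogenetic tree to Newick with fixed-precision branch lengths
#'
#' Branch lengths are written with six decimal places so output files are
#' byte-stable across platforms.
#'
#' @param tree An `ape::phylo` object.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned instead of written.
#' @return The Newick string, invisibly when written to `path`.
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:2);")
#' write_newick(tr)
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  bl <- tree$edge.length
  fmt <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) {
      return(tree$tip.label[node])
    }
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2]
      len <- if (is.null(bl)) "" else sprintf(":%.6f", bl[r])
      paste0(fmt(child), len)
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(fmt(root), ";")
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(txt)
}

#' Write a table as TSV with a header row
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Write an object as pretty-printed, key-sorted JSON
#'
#' Keys are sorted recursively so that identical objects always serialize to
#' identical bytes, which makes the files usable in golden tests.
#'
#' @param obj A list (or atomic) object to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_stable <- function(obj, path) {
  sort_keys <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x)) && all(nzchar(names(x)))) {
        x <- x[order(names(x))]
      }
      lapply(x, sort_keys)
    } else {
      x
    }
  }
  jsonlite::write_json(sort_keys(obj), path, pretty = TRUE,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# -- internal sequence helpers ------------------------------------------------

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

check_nucleotides <- function(x, what = "sequence", allow_n = TRUE) {
  ok <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(ok, x)
  if (any(bad)) {
    stop(what, " contains characters outside ",
         if (allow_n) "A/C/G/T/N" else "A/C/G/T", call. = FALSE)
  }
  invisible(x)
}
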