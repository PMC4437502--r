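#' Construct a per-locus sequence set
#'
#' A \code{locus_alignment} holds the allele fragments observed at one locus:
#' an ordered, named set of equal-length uppercase DNA sequences, one per
#' isolate.  Allele identity is exact string match, so by default only the
#' unambiguous bases A, C, G, T are accepted; records carrying N or IUPAC
#' ambiguity codes make allele calling ill-defined and are rejected
#' (\code{alphabet = "strict"}) or dropped with a warning
#' (\code{alphabet = "lenient"}).
#'
#' @param sequences named character vector of DNA sequences; names are
#'   isolate ids.  Sequences are uppercased before any comparison.
#' @param locus locus name.
#' @param alphabet \code{"strict"} (default) or \code{"lenient"}.
#' @return An object of class \code{locus_alignment}.
#' @export
locus_alignment <- function(sequences, locus, alphabet = c("strict", "lenient")) {
  alphabet <- match.arg(alphabet)
  if (length(sequences) == 0L)
    stop("empty sequence set for locus '", locus, "'")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must carry an isolate id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate isolate id(s) at locus '", locus, "': ",
         paste(unique(dup), collapse = ", "))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad)) {
    if (alphabet == "strict")
      stop("non-ACGT characters at locus '", locus, "' in record(s): ",
           paste(ids[bad], collapse = ", "),
           " (use alphabet = \"lenient\" to drop them)")
    warning("dropping ", sum(bad), " record(s) with ambiguous bases at locus '",
            locus, "': ", paste(ids[bad], collapse = ", "))
    sequences <- sequences[!bad]
    ids <- ids[!bad]
    if (!length(sequences)) stop("no records left at locus '", locus, "'")
  }
  len <- nchar(sequences)
  if (length(unique(len)) > 1L) {
    off <- ids[len != len[1L]][1L]
    stop("sequence length mismatch at locus '", locus, "': record '", off,
         "' has ", nchar(sequences[[off]]), " bp, expected ", len[1L])
  }
  structure(list(locus = locus, sequences = sequences),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus_alignment '", x$locus, "': ", length(x$sequences),
      " sequences x ", nchar(x$sequences[[1L]]), " bp\n", sep = "")
  invisible(x)
}

#' Number of sequences / fragment length of a locus alignment
#' @param x a \code{locus_alignment}.
#' @return integer.
#' @rdname locus_alignment_dims
#' @export
n_seqs <- function(x) length(x$sequences)

#' @rdname locus_alignment_dims
#' @export
seq_length <- function(x) nchar(x$sequences[[1L]])

## character matrix view (rows = isolates, cols = sites); used by the
## diversity statistics
aln_matrix <- function(x) {
  m <- do.call(rbind, strsplit(unname(x$sequences), "", fixed = TRUE))
  rownames(m) <- names(x$sequences)
  m
}

#' Read one locus from a FASTA file
#'
#' Headers are truncated at the first whitespace to form isolate ids; record
#' order is preserved.  Errors name the offending record for duplicate ids
#' and within-locus length mismatches.
#'
#' @param path path to a FASTA file.
#' @param locus locus name; defaults to the file name without extension.
#' @param alphabet see \code{\link{locus_alignment}}.
#' @return A \code{locus_alignment}.
#' @export
read_locus_fasta <- function(path, locus = NULL,
                             alphabet = c("strict", "lenient")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (length(dna) == 0L) stop("empty FASTA file: ", path)
  seqs <- vapply(as.character(dna), paste0, "", collapse = "")
  names(seqs) <- sub("\\s.*$", "", names(dna))
  locus_alignment(seqs, locus, alphabet = match.arg(alphabet))
}

#' Write a locus alignment to FASTA
#' @param x a \code{locus_alignment} (or any named character vector of
#'   sequences).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_locus_fasta <- function(x, path) {
  seqs <- if (inherits(x, "locus_alignment")) x$sequences else x
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con)
  invisible(path)
}

#' Read an allelic-profile table
#'
#' PubMLST-style tab-separated table: header \code{isolate} followed by one
#' column per locus in scheme order; an optional trailing \code{ST} column is
#' ignored.  Allele numbers must be positive integers.
#'
#' @param path path to a TSV file.
#' @param scheme an \code{mlst_scheme}.
#' @return A data frame with column \code{isolate} and one integer column per
#'   locus, in scheme order.
#' @export
read_profile_table <- function(path, scheme) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(c("isolate", scheme$locus), names(tab))
  if (length(missing))
    stop("profile table is missing column(s): ",
         paste(missing, collapse = ", "))
  out <- tab[, c("isolate", scheme$locus)]
  for (loc in scheme$locus) {
    v <- out[[loc]]
    iv <- suppressWarnings(as.integer(v))
    bad <- which(is.na(iv) | iv != suppressWarnings(as.numeric(v)))
    if (length(bad))
      stop("non-integer allele in column '", loc, "', row ", bad[1L],
           " (value '", v[bad[1L]], "')")
    if (any(iv <= 0L))
      stop("allele numbers must be positive (column '", loc, "')")
    out[[loc]] <- iv
  }
  out
}

#' Write an allelic-profile table
#' @param profiles data frame as returned by \code{\link{read_profile_table}},
#'   or the \code{profiles} matrix of an \code{\link{mlst_typing}} object.
#' @param path output path.
#' @param st optional integer vector of ST numbers appended as a final column.
#' @return \code{path}, invisibly.
#' @export
write_profile_table <- function(profiles, path, st = NULL) {
  df <- as.data.frame(profiles)
  if (!is.null(st)) df$ST <- as.integer(st)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree in Newick format
#' @param tree an \code{ape} \code{phylo} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a split system as a SplitsTree-compatible Nexus file
#'
#' Emits \code{TAXA} and \code{Splits} blocks in the SplitsTree 4 dialect:
#' each split is listed by its weight (isolation index) and the taxon indices
#' of one side of the bipartition.
#'
#' @param splits a \code{\link{split_decomposition}} result (class
#'   \code{split_set}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_nexus_splits <- function(splits, path) {
  taxa <- splits$taxa
  n <- length(taxa)
  ns <- length(splits$splits)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#nexus")
  w("")
  w("BEGIN Taxa;")
  w("DIMENSIONS ntax=", n, ";")
  w("TAXLABELS")
  for (i in seq_len(n)) w("[", i, "] '", taxa[i], "'")
  w(";")
  w("END; [Taxa]")
  w("")
  w("BEGIN Splits;")
  w("DIMENSIONS ntax=", n, " nsplits=", ns, ";")
  w("FORMAT labels=no weights=yes confidences=no intervals=no;")
  w("PROPERTIES fit=", formatC(splits$fit, format = "f", digits = 2),
    " weakly compatible cyclic;")
  w("MATRIX")
  i <- 0L
  for (s in splits$splits) {
    i <- i + 1L
    side <- which(taxa %in% s$side)
    w("[", i, ", size=", length(side), "]\t",
      formatC(s$weight, format = "g", digits = 10), "\t",
      paste(side, collapse = " "), ",")
  }
  w(";")
  w("END; [Splits]")
  invisible(path)
}

#' Write an analysis report (or any stats list) as JSON
#' @param stats a list of results.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
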