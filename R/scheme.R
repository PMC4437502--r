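#' Define an MLST typing scheme
#'
#' A scheme is an ordered set of housekeeping-gene loci together with the
#' expected fragment length of each locus.  All downstream structures
#' (allelic profiles, concatenated alignments) follow the locus order given
#' here.
#'
#' @param loci character vector of locus names (unique, non-empty, length
#'   at least 2).
#' @param fragment_lengths integer vector of expected fragment sizes in bp,
#'   one per locus, all positive.
#' @param positions optional character vector of reference genome positions
#'   (informational only; never used to slice sequences).
#' @return An object of class \code{mlst_scheme}: a data frame with columns
#'   \code{locus}, \code{length} and optionally \code{position}.
#' @examples
#' sch <- mlst_scheme(c("recA", "rpoB"), c(647L, 715L))
#' n_loci(sch)
#' @export
mlst_scheme <- function(loci, fragment_lengths, positions = NULL) {
  loci <- as.character(loci)
  if (length(loci) < 2L)
    stop("a scheme needs at least 2 loci")
  if (anyDuplicated(loci) || any(!nzchar(loci)))
    stop("locus names must be unique and non-empty")
  fragment_lengths <- as.integer(fragment_lengths)
  if (length(fragment_lengths) != length(loci))
    stop("one fragment length per locus required")
  if (any(is.na(fragment_lengths)) || any(fragment_lengths <= 0L))
    stop("fragment lengths must be positive integers")
  df <- data.frame(locus = loci, length = fragment_lengths,
                   stringsAsFactors = FALSE)
  if (!is.null(positions)) df$position <- as.character(positions)
  class(df) <- c("mlst_scheme", "data.frame")
  df
}

#' Number of loci in a scheme
#' @param scheme an \code{mlst_scheme}.
#' @return integer count of loci.
#' @export
n_loci <- function(scheme) nrow(scheme)

#' The 11-locus Lactobacillus fermentum scheme
#'
#' The published typing scheme for \emph{Limosilactobacillus (Lactobacillus)
#' fermentum}: eleven housekeeping-gene fragments with sizes between 589 bp
#' (\emph{dnaA}) and 748 bp (\emph{uvrC}), 7592 bp in total.  Positions refer
#' to the \emph{L. fermentum} IFO 3956 reference genome and are informational.
#'
#' @return An \code{mlst_scheme} with 11 loci.
#' @examples
#' sum(lf_scheme()$length)  # 7592
#' @export
lf_scheme <- function() {
  mlst_scheme(
    loci = c("clpX", "dnaA", "dnaK", "groEL", "murC", "murE",
             "pepX", "pyrG", "recA", "rpoB", "uvrC"),
    fragment_lengths = c(659L, 589L, 734L, 663L, 745L, 659L,
                         724L, 709L, 647L, 715L, 748L),
    positions = c("723485-724143", "410-998", "885345-886078",
                  "394357-395019", "1501098-1500354", "2086362-2085704",
                  "1895783-1896506", "246712-247420", "605296-605942",
                  "1719594-1718880", "727309-728056")
  )
}

#' Read a scheme definition from a YAML config file
#'
#' The file must contain a \code{loci} list, each entry a mapping with
#' \code{name} and \code{length} keys (and optional \code{position}).
#'
#' @param path path to a YAML file.
#' @return An \code{mlst_scheme}.
#' @export
read_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$loci)) stop("scheme config must have a 'loci' list")
  nm <- vapply(cfg$loci, function(x) as.character(x$name), "")
  ln <- vapply(cfg$loci, function(x) as.integer(x$length), 0L)
  pos <- vapply(cfg$loci, function(x)
    if (is.null(x$position)) NA_character_ else as.character(x$position), "")
  mlst_scheme(nm, ln, positions = if (all(is.na(pos))) NULL else pos)
}

#' Write a scheme definition to a YAML config file
#' @param scheme an \code{mlst_scheme}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  loci <- lapply(seq_len(nrow(scheme)), function(i) {
    x <- list(name = scheme$locus[i], length = scheme$length[i])
    if (!is.null(scheme$position)) x$position <- scheme$position[i]
    x
  })
  yaml::write_yaml(list(loci = loci), path)
  invisible(path)
}

#' @export
print.mlst_scheme <- function(x, ...) {
  cat("MLST scheme:", nrow(x), "loci,", sum(x$length), "bp total\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
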