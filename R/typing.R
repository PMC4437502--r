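#' Create an empty allele catalog
#'
#' The catalog is a per-locus registry mapping each distinct fragment
#' sequence to a positive integer allele number.  Numbers are assigned
#' 1, 2, ... in order of first observation, so they are stable labels of the
#' input order, not biologically meaningful ranks; every downstream statistic
#' is invariant to relabelling.  The catalog is environment-backed so that
#' \code{\link{call_allele}} can register new alleles in place.
#'
#' @return An object of class \code{allele_catalog}.
#' @export
allele_catalog <- function() {
  env <- new.env(parent = emptyenv())
  env$seqs <- list()    # locus -> character vector, index = allele number
  env$index <- list()   # locus -> named int vector keyed by sequence
  class(env) <- "allele_catalog"
  env
}

#' @export
print.allele_catalog <- function(x, ...) {
  k <- vapply(x$seqs, length, 0L)
  cat("allele_catalog:", length(k), "loci")
  if (length(k)) cat(" (", paste0(names(k), "=", k, collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Alleles registered at a locus
#' @param catalog an \code{allele_catalog}.
#' @param locus locus name.
#' @return character vector of sequences; element \code{i} is allele \code{i}.
#' @export
catalog_alleles <- function(catalog, locus) {
  s <- catalog$seqs[[locus]]
  if (is.null(s)) character(0) else s
}

#' Assign an allele number to a sequence
#'
#' Exact-match lookup against the catalog.  In \code{assign_new} mode an
#' unseen sequence receives the next integer and is registered; in
#' \code{strict} mode an unseen sequence is an error.  Submitting the same
#' sequence twice always yields the same number.
#'
#' @param sequence a DNA string (A/C/G/T; uppercased before comparison).
#' @param locus locus name.
#' @param catalog an \code{allele_catalog}; updated in place in
#'   \code{assign_new} mode.
#' @param mode \code{"assign_new"} (default) or \code{"strict"}.
#' @param revcomp_canonical if \code{TRUE}, the sequence is canonicalised to
#'   the lexicographic minimum of itself and its reverse complement before
#'   lookup (for inputs of mixed orientation; off by default).
#' @return integer allele number.
#' @export
call_allele <- function(sequence, locus, catalog,
                        mode = c("assign_new", "strict"),
                        revcomp_canonical = FALSE) {
  mode <- match.arg(mode)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("invalid characters in sequence at locus '", locus, "'")
  if (revcomp_canonical) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(sequence, "")[[1L]]),
                                       collapse = ""))
    sequence <- min(sequence, rc)
  }
  known <- catalog$seqs[[locus]]
  if (!is.null(known) && nchar(sequence) != nchar(known[1L]))
    stop("sequence length ", nchar(sequence), " does not match locus '",
         locus, "' fragment length ", nchar(known[1L]))
  hit <- catalog$index[[locus]][sequence]
  if (!is.null(known) && length(hit) && !is.na(hit))
    return(unname(hit))
  if (mode == "strict")
    stop("unseen allele sequence at locus '", locus, "' (strict mode)")
  num <- length(known) + 1L
  catalog$seqs[[locus]] <- c(known, sequence)
  idx <- catalog$index[[locus]]
  if (is.null(idx)) idx <- integer(0)
  idx[sequence] <- num
  catalog$index[[locus]] <- idx
  num
}

#' Create an empty sequence-type database
#'
#' Maintains the bijection between allelic profiles (integer vectors of
#' length L, in scheme locus order) and ST numbers 1, 2, ... assigned in
#' order of first observation.
#'
#' @param n_loci profile length L.
#' @return An object of class \code{st_database} (environment-backed).
#' @export
st_database <- function(n_loci) {
  env <- new.env(parent = emptyenv())
  env$n_loci <- as.integer(n_loci)
  env$profiles <- matrix(integer(0), nrow = 0L, ncol = n_loci)
  env$index <- integer(0)  # named by profile key
  class(env) <- "st_database"
  env
}

profile_key <- function(profile) paste(profile, collapse = "-")

#' Assign a sequence type to an allelic profile
#'
#' Identical profiles always map to the same ST; profiles differing at any
#' locus map to distinct STs.  In \code{assign_new} mode a new profile
#' receives the next ST number; in \code{strict} mode it is an error.
#'
#' @param profile integer vector of allele numbers, in scheme locus order.
#' @param db an \code{st_database}; updated in place in \code{assign_new}
#'   mode.
#' @param mode \code{"assign_new"} (default) or \code{"strict"}.
#' @return integer ST number.
#' @export
assign_st <- function(profile, db, mode = c("assign_new", "strict")) {
  mode <- match.arg(mode)
  profile <- as.integer(profile)
  if (length(profile) != db$n_loci)
    stop("profile length ", length(profile), " != scheme loci ", db$n_loci)
  if (any(is.na(profile)) || any(profile < 1L))
    stop("allele numbers must be positive integers")
  key <- profile_key(profile)
  hit <- db$index[key]
  if (length(hit) && !is.na(hit)) return(unname(hit))
  if (mode == "strict") stop("unseen allelic profile (strict mode)")
  st <- nrow(db$profiles) + 1L
  db$profiles <- rbind(db$profiles, profile)
  db$index[key] <- st
  st
}

#' @export
print.st_database <- function(x, ...) {
  cat("st_database:", nrow(x$profiles), "STs over", x$n_loci, "loci\n")
  invisible(x)
}

#' Type a set of isolates at every scheme locus
#'
#' The end-to-end typing step: assigns allele numbers per locus (order of
#' first observation) and sequence types from the resulting allelic
#' profiles.  Every isolate must be present at every locus.
#'
#' @param sequence_sets list of \code{\link{locus_alignment}} objects, one
#'   per scheme locus (any order; matched by locus name).
#' @param scheme an \code{mlst_scheme}.
#' @param metadata optional data frame with an \code{isolate} column and
#'   arbitrary annotation columns (e.g. source category, geography) carried
#'   through to the isolate table.
#' @return An object of class \code{mlst_typing} with elements:
#'   \describe{
#'     \item{scheme}{the scheme used}
#'     \item{catalog}{the \code{\link{allele_catalog}}}
#'     \item{profiles}{integer matrix, one row per ST (rownames = ST
#'       numbers), columns = loci}
#'     \item{isolates}{data frame \code{isolate}, one allele column per
#'       locus, \code{ST}, plus any metadata columns}
#'     \item{st_counts}{named integer vector, isolates per ST}
#'   }
#' @examples
#' a <- locus_alignment(c(i1 = "ACGT", i2 = "ACGA"), "locA")
#' b <- locus_alignment(c(i1 = "TTGG", i2 = "TTGG"), "locB")
#' ty <- build_typing_database(list(a, b), mlst_scheme(c("locA", "locB"), c(4, 4)))
#' ty$st_counts
#' @export
build_typing_database <- function(sequence_sets, scheme, metadata = NULL) {
  names(sequence_sets) <- vapply(sequence_sets, function(x) x$locus, "")
  missing_loci <- setdiff(scheme$locus, names(sequence_sets))
  if (length(missing_loci))
    stop("no sequences for scheme locus/loci: ",
         paste(missing_loci, collapse = ", "))
  sequence_sets <- sequence_sets[scheme$locus]
  ids <- names(sequence_sets[[1L]]$sequences)
  missing <- character(0)
  for (ss in sequence_sets) {
    gone <- setdiff(ids, names(ss$sequences))
    extra <- setdiff(names(ss$sequences), ids)
    if (length(gone))
      missing <- c(missing, paste0("(", gone, ", ", ss$locus, ")"))
    if (length(extra))
      missing <- c(missing, paste0("(", extra, ", only in ", ss$locus, ")"))
  }
  if (length(missing))
    stop("isolates missing from some loci: ", paste(missing, collapse = " "))

  catalog <- allele_catalog()
  prof <- matrix(0L, nrow = length(ids), ncol = nrow(scheme),
                 dimnames = list(ids, scheme$locus))
  for (ss in sequence_sets)
    for (id in ids)
      prof[id, ss$locus] <- call_allele(ss$sequences[[id]], ss$locus, catalog)

  db <- st_database(nrow(scheme))
  st <- integer(length(ids))
  for (i in seq_along(ids)) st[i] <- assign_st(prof[i, ], db)

  iso <- data.frame(isolate = ids, prof, ST = st,
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  if (!is.null(metadata)) {
    if (!"isolate" %in% names(metadata))
      stop("metadata must have an 'isolate' column")
    iso <- merge(iso, metadata, by = "isolate", all.x = TRUE, sort = FALSE)
    iso <- iso[match(ids, iso$isolate), , drop = FALSE]
    rownames(iso) <- NULL
  }
  st_counts <- table(factor(st, levels = seq_len(nrow(db$profiles))))
  st_counts <- stats::setNames(as.integer(st_counts), seq_len(nrow(db$profiles)))
  rownames(db$profiles) <- seq_len(nrow(db$profiles))
  structure(list(scheme = scheme, catalog = catalog,
                 profiles = db$profiles, isolates = iso,
                 st_counts = st_counts),
            class = "mlst_typing")
}

#' @export
print.mlst_typing <- function(x, ...) {
  cat("MLST typing of", nrow(x$isolates), "isolates at",
      nrow(x$scheme), "loci\n")
  cat("  STs:", nrow(x$profiles),
      " (singleton STs:", sum(x$st_counts == 1L), ")\n")
  top <- sort(x$st_counts, decreasing = TRUE)[1L]
  cat("  largest ST:", names(top), "with", top, "isolates\n")
  invisible(x)
}

#' @export
summary.mlst_typing <- function(object, ...) {
  spectrum <- sort(object$st_counts, decreasing = TRUE)
  alleles <- vapply(object$scheme$locus,
                    function(l) length(catalog_alleles(object$catalog, l)), 0L)
  out <- list(n_isolates = nrow(object$isolates),
              n_st = nrow(object$profiles),
              n_singleton_st = sum(object$st_counts == 1L),
              largest_st = as.integer(names(spectrum)[1L]),
              largest_st_count = unname(spectrum[1L]),
              st_spectrum = spectrum,
              alleles_per_locus = alleles)
  class(out) <- "summary.mlst_typing"
  out
}

#' @export
print.summary.mlst_typing <- function(x, ...) {
  cat(x$n_isolates, " isolates -> ", x$n_st, " STs; ",
      x$n_singleton_st, " singleton STs; largest ST-", x$largest_st,
      " (", x$largest_st_count, " isolates)\n", sep = "")
  cat("alleles per locus:\n")
  print(x$alleles_per_locus)
  invisible(x)
}

#' Extract the per-isolate profile matrix from a typing result
#' @param typing an \code{mlst_typing}.
#' @return integer matrix, rows = isolates, columns = loci.
#' @export
isolate_profiles <- function(typing) {
  m <- as.matrix(typing$isolates[, typing$scheme$locus, drop = FALSE])
  rownames(m) <- typing$isolates$isolate
  storage.mode(m) <- "integer"
  m
}
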