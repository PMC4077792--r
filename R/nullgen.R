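#' Specification for a composition-matched random null set
#'
#' The null model of the constraint test: random sequences whose lengths
#' reproduce a reference set one-to-one and whose pooled GC content matches
#' the pooled GC of the references.
#'
#' @param lengths integer vector of sequence lengths (nt), all >= 1.
#' @param gc_target pooled G+C fraction in `[0, 1]`.
#' @param seed integer seed making generation reproducible.
#' @return object of class `null_spec`.
#' @export
null_spec <- function(lengths, gc_target, seed = 1L) {
  lengths <- as.integer(lengths)
  if (any(lengths < 1)) stop("all lengths must be >= 1")
  if (gc_target < 0 || gc_target > 1) stop("gc_target must be in [0, 1]")
  structure(list(lengths = lengths, gc_target = gc_target,
                 seed = as.integer(seed)),
            class = "null_spec")
}

#' Generate GC- and length-matched random sequences
#'
#' One sequence per requested length, of exactly that length. Per sequence
#' the G+C count is fixed at `round(length * gc_target)` and placed uniformly
#' at random; G/C and A/U split their allocations uniformly. The pooled GC of
#' the output therefore deviates from the target only by per-sequence
#' rounding, bounded by `0.5 * n_sequences / total_length`.
#'
#' @param spec a [null_spec()].
#' @param prefix id prefix for the generated records.
#' @return record table with `region = "RANDOM"`.
#' @export
generate_matched <- function(spec, prefix = "random") {
  stopifnot(inherits(spec, "null_spec"))
  with_seed(spec$seed, {
    res <- vapply(spec$lengths, function(len) {
      n_gc <- round(len * spec$gc_target)
      bases <- sample(c("A", "U"), len, replace = TRUE)
      gc_pos <- sample.int(len, n_gc)
      bases[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
      paste(bases, collapse = "")
    }, character(1))
    sequence_records(sprintf("%s_%03d", prefix, seq_along(res)), res,
                     region = "RANDOM")
  })
}

#' Derive a null specification from reference sequences
#'
#' Copies the reference lengths one-to-one and sets the GC target to the
#' pooled (overall) GC fraction of the references.
#'
#' @param refs record table of reference sequences.
#' @param seed seed stored in the returned spec.
#' @export
match_from_reference <- function(refs, seed = 1L) {
  if (!is.data.frame(refs) || nrow(refs) == 0)
    stop("reference set must be a non-empty record table")
  null_spec(nchar(refs$residues), gc_fraction(refs), seed = seed)
}

#' Pooled G+C fraction of sequences
#'
#' @param x a record table or character vector of sequences.
#' @export
gc_fraction <- function(x) {
  seqs <- if (is.data.frame(x)) x$residues else x
  chars <- unlist(strsplit(toupper(seqs), ""))
  sum(chars %in% c("G", "C")) / length(chars)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
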