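#' Scaffold specification for structure-constrained synthetic sequences
#'
#' Describes an ITS-like sequence built from `k_hairpins` designed stem-loop
#' units separated by pairing-resistant spacers. These sequences stand in
#' for real spacers whose folds are under selective constraint: their ground
#' truth (the intended structure and hairpin count) is known by
#' construction, which makes every later pipeline stage testable without
#' real data.
#'
#' @param k_hairpins number of stem-loop units (>= 0).
#' @param stem_len base pairs per designed stem (Watson-Crick only, so the
#'   intended fold is strongly favored).
#' @param loop_len unpaired bases in each designed loop (>= 3).
#' @param spacer_len unpaired spacer length between units (>= 0).
#' @param gc_target overall G+C fraction of the finished sequence; spacers
#'   and loops are A/U-rich (75%) to resist spurious pairing, and the stems
#'   absorb the remaining G+C budget.
#' @param seed RNG seed.
#' @return object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(k_hairpins, stem_len = 8, loop_len = 5,
                          spacer_len = 10, gc_target = 0.549, seed = 1L) {
  stopifnot(k_hairpins >= 0, stem_len >= 1, loop_len >= 3, spacer_len >= 0,
            gc_target >= 0, gc_target <= 1)
  structure(list(k_hairpins = as.integer(k_hairpins),
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len),
                 spacer_len = as.integer(spacer_len),
                 gc_target = gc_target, seed = as.integer(seed)),
            class = "scaffold_spec")
}

COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

revcomp <- function(x) {
  paste(rev(COMPLEMENT[strsplit(x, "")[[1]]]), collapse = "")
}

kmers <- function(s, k) if (nchar(s) < k) character(0) else
  substring(s, 1:(nchar(s) - k + 1), k:nchar(s))

# all k-mers that could base-pair with `m` in antiparallel orientation,
# counting both Watson-Crick and GU wobble pairs
PAIR_PARTNERS <- list(A = "U", U = c("A", "G"), G = c("C", "U"), C = "G")

pairable_partners <- function(m) {
  ch <- rev(strsplit(m, "")[[1]])
  apply(do.call(expand.grid, PAIR_PARTNERS[ch]), 1, paste, collapse = "")
}

# how many 4-mers of `spacer` could pair (WC or wobble) with a 4-mer of the
# already-built sequence context?
complementarity_hits <- function(spacer, context, k = 4) {
  if (nchar(spacer) < k || !length(context)) return(0L)
  ctx <- unique(unlist(lapply(context, kmers, k = k)))
  sum(vapply(kmers(spacer, k),
             function(m) any(pairable_partners(m) %in% ctx), logical(1)))
}

#' Generate one structure-constrained synthetic sequence
#'
#' Builds `spacer (stem5' loop stem3')+ spacer` with `stem3'` the reverse
#' complement of `stem5'`. Spacer and loop bases are drawn A/U-rich and each
#' spacer is reshuffled (up to 50 attempts) until none of its 4-mers is
#' complementary to any stem 4-mer; the stems carry whatever G+C the
#' `gc_target` requires beyond the A/U-rich background. The intended
#' structure is returned as ground truth.
#'
#' @param spec a [scaffold_spec()].
#' @param id record identifier.
#' @param seed optional seed overriding the spec's.
#' @return list with `record` (one-row record table, `region = "SYNTH"`) and
#'   `intended` (the designed [secondary_structure()]).
#' @export
make_structured <- function(spec, id = "synth_1", seed = spec$seed) {
  k <- spec$k_hairpins; s <- spec$stem_len
  l <- spec$loop_len; sp <- spec$spacer_len
  L <- k * (2 * s + l) + (k + 1) * sp
  if (L < 1) stop("scaffold has zero length")
  with_seed(seed, {
    # G+C budget: exactly round(L * gc_target) bases, absorbed by the stems
    # first (each G-C pair holds two), then the loops, and only then the
    # spacers -- the segments whose pairing potential matters most stay as
    # A/U-rich as the target permits. Among A/U the draw is A-heavy so that
    # scarce U makes spurious A-U helices between unpaired segments rare.
    # G+C budget: exactly round(L * gc_target) bases. Stems absorb most of it
    # (each G-C pair holds two bases) but are capped at 75% G-C pairs --
    # all-G/C stems are unavoidably complementary to one another and zip
    # across units -- then loops, then spacers. Among A/U the draw is A-heavy
    # so that scarce U keeps spurious A-U helices between unpaired segments
    # rare.
    need_gc <- round(L * spec$gc_target)
    if (need_gc > L) stop("impossible composition: gc_target unreachable")
    n_loop <- k * l; n_sp <- (k + 1) * sp
    gc_pairs <- if (k > 0) min(floor(0.75 * k * s), floor(need_gc / 2)) else 0L
    if (need_gc - 2L * gc_pairs > n_loop + n_sp)  # raise the cap if it must
      gc_pairs <- min(k * s, ceiling((need_gc - n_loop - n_sp) / 2))
    loop_gc <- min(n_loop, need_gc - 2L * gc_pairs)
    sp_gc <- need_gc - 2L * gc_pairs - loop_gc
    if (sp_gc > n_sp) stop("impossible composition: gc_target unreachable")

    # rearrange a segment until none of its 4-mers can pair (Watson-Crick or
    # wobble) with anything already placed: random restarts, then base swaps
    context <- character(0)
    shuffle_resistant <- function(bases) {
      if (!length(bases)) return(bases)
      hits_of <- function(b) complementarity_hits(paste(b, collapse = ""),
                                                  context)
      best <- bases; best_hits <- hits_of(bases)
      tries <- 0
      while (best_hits > 0 && tries < 60) {
        cand <- sample(bases)
        h <- hits_of(cand)
        if (h < best_hits) { best <- cand; best_hits <- h }
        tries <- tries + 1
      }
      swaps <- 0
      while (best_hits > 0 && swaps < 200 && length(bases) > 1) {
        cand <- best
        ij <- sample.int(length(cand), 2)
        cand[ij] <- cand[rev(ij)]
        h <- hits_of(cand)
        if (h <= best_hits) { best <- cand; best_hits <- h }
        swaps <- swaps + 1
      }
      best
    }

    stems <- list()
    if (k > 0) {
      quota <- diff(round(seq(0, gc_pairs, length.out = k + 1)))
      for (m in seq_len(k)) {
        bases <- c(sample(c("G", "C"), quota[m], replace = TRUE),
                   sample(c("A", "U"), s - quota[m], replace = TRUE))
        bases <- shuffle_resistant(sample(bases))
        stems[[m]] <- paste(bases, collapse = "")
        context <- c(context, stems[[m]], revcomp(stems[[m]]))
      }
    }
    draw_segment_bases <- function(n, n_gc) {
      if (n == 0) return(character(0))
      bases <- sample(c("A", "U"), n, replace = TRUE, prob = c(0.7, 0.3))
      if (n_gc > 0)
        bases[sample.int(n, n_gc)] <- sample(c("G", "C"), n_gc, replace = TRUE)
      bases
    }
    chop <- function(bases, len, count) {
      if (count == 0 || len == 0) return(rep(list(character(0)), count))
      split(bases, rep(seq_len(count), each = len))
    }
    place <- function(segs) lapply(segs, function(b) {
      out <- shuffle_resistant(b)
      if (length(out)) context <<- c(context, paste(out, collapse = ""))
      out
    })
    loops <- place(chop(draw_segment_bases(n_loop, loop_gc), l, k))
    spacers <- place(chop(draw_segment_bases(n_sp, sp_gc), sp, k + 1))
    parts <- character(0)
    pairs <- matrix(integer(0), 0, 2)
    pos <- 0L
    for (m in seq_len(k + 1)) {
      parts <- c(parts, paste(spacers[[m]], collapse = ""))
      pos <- pos + sp
      if (m <= k) {
        o <- pos + 1L  # unit start
        parts <- c(parts, stems[[m]], paste(loops[[m]], collapse = ""),
                   revcomp(stems[[m]]))
        pairs <- rbind(pairs, cbind(o + seq_len(s) - 1L,
                                    o + 2L * s + l - seq_len(s)))
        pos <- pos + 2L * s + l
      }
    }
    seqstr <- paste(parts, collapse = "")
    stopifnot(nchar(seqstr) == L)
    record <- sequence_records(id, seqstr, region = "SYNTH")
    intended <- secondary_structure(pairs, L, seq_id = id)
    list(record = record, intended = intended)
  })
}

#' Generate a labeled synthetic dataset of structured vs random sequences
#'
#' The structured class comes from [make_structured()] with per-sequence
#' jittered spacer lengths; the random class is generated by the null model
#' matched one-to-one to the structured class's lengths and pooled GC.
#' Mirrors the real study design: a set of putatively constrained sequences
#' against a composition-matched unconstrained baseline.
#'
#' @param n_structured,n_random class sizes (the random class recycles the
#'   structured lengths if sizes differ).
#' @param spec base [scaffold_spec()].
#' @param seed master seed for the whole dataset.
#' @param jitter spacer lengths vary uniformly in `spacer_len +/- jitter`.
#' @return list with `records` (combined record table) and `truth`
#'   (data frame: `seq_id`, `class`, `half`, `k_intended`, `length`).
#' @export
make_dataset <- function(n_structured, n_random, spec, seed = 1L,
                         jitter = 3L) {
  stopifnot(n_structured >= 1, n_random >= 1)
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n_structured + 1)
    sp_lens <- pmax(0L, spec$spacer_len +
                      sample(seq(-jitter, jitter), n_structured, replace = TRUE))
    structured <- lapply(seq_len(n_structured), function(m) {
      sp_m <- scaffold_spec(spec$k_hairpins, spec$stem_len, spec$loop_len,
                            sp_lens[m], spec$gc_target, seed = seeds[m])
      make_structured(sp_m, id = sprintf("synth_%03d", m))
    })
    srec <- do.call(rbind, lapply(structured, `[[`, "record"))
    nspec <- match_from_reference(srec, seed = seeds[n_structured + 1])
    nspec$lengths <- rep_len(nspec$lengths, n_random)
    rrec <- generate_matched(nspec)
    truth <- rbind(
      data.frame(seq_id = srec$id, class = "SYNTH", half = "matched",
                 k_intended = spec$k_hairpins, length = nchar(srec$residues)),
      data.frame(seq_id = rrec$id, class = "RANDOM", half = "matched",
                 k_intended = NA_integer_, length = nchar(rrec$residues)))
    list(records = rbind(srec, rrec), truth = truth,
         intended = lapply(structured, `[[`, "intended"))
  })
}

#' An ITS-like two-half synthetic study
#'
#' Convenience design mirroring the real data's layout: half the structured
#' sequences are ITS1-like (6 stem-loop units, ~260 nt) and half ITS2-like
#' (4 units, ~185 nt), each with a matched random partner, giving the
#' two-factor (class x half) table the comparison statistics expect.
#'
#' @param n_per_class sequences per class (even; split over the two halves).
#' @param gc_target overall GC fraction for both halves.
#' @param seed master seed.
#' @param jitter spacer-length jitter passed to [make_dataset()].
#' @return list with `records`, `truth`, `intended` as in [make_dataset()].
#' @export
its_like_dataset <- function(n_per_class = 50, gc_target = 0.549, seed = 1L,
                             jitter = 3L) {
  stopifnot(n_per_class >= 2, n_per_class %% 2 == 0)
  n2 <- n_per_class / 2
  d1 <- make_dataset(n2, n2, scaffold_spec(6, 8, 5, 20, gc_target),
                     seed = seed, jitter = jitter)
  d2 <- make_dataset(n2, n2, scaffold_spec(4, 8, 5, 20, gc_target),
                     seed = seed + 1L, jitter = jitter)
  fix <- function(d, half, tag) {
    d$records$id <- paste0(tag, "_", d$records$id)
    d$truth$seq_id <- paste0(tag, "_", d$truth$seq_id)
    d$truth$half <- half
    d
  }
  d1 <- fix(d1, "ITS1like", "h1")
  d2 <- fix(d2, "ITS2like", "h2")
  list(records = rbind(d1$records, d2$records),
       truth = rbind(d1$truth, d2$truth),
       intended = c(d1$intended, d2$intended))
}
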