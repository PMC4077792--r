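#' Nearest-neighbor thermodynamic energy model
#'
#' Loads a 37 degC nearest-neighbor parameter set from plain-text tables:
#' helix stacking free energies per ordered pair of adjacent base pairs,
#' loop-length initiation penalties for hairpin/bulge/internal loops, an
#' affine multibranch-loop model, and a terminal AU/GU helix-end penalty.
#' Allowed pairs are AU, UA, GC, CG, GU, UG. Loop tables beyond the last
#' tabulated size are extrapolated logarithmically; all folding arithmetic
#' is done in integer tenths of kcal/mol to keep the dynamic program exact.
#'
#' The default tables shipped with the package are a published Turner-style
#' set rounded to 0.1 kcal/mol. The whole model is swappable: point
#' `param_dir` at any directory with the same three-file schema
#' (`stack.tsv`, `loops.tsv`, `misc.tsv`).
#'
#' @param param_dir directory containing the parameter tables.
#' @param max_length longest sequence the precomputed integer tables cover;
#'   tables are re-extended automatically for longer input.
#' @return an object of class `energy_model`.
#' @export
energy_model <- function(param_dir = NULL, max_length = 320) {
  if (is.null(param_dir))
    param_dir <- system.file("extdata", "nn_params", package = "spacerfold")
  stack <- read.delim(file.path(param_dir, "stack.tsv"), comment.char = "#")
  loops <- read.delim(file.path(param_dir, "loops.tsv"), comment.char = "#")
  misc <- read.delim(file.path(param_dir, "misc.tsv"), comment.char = "#")
  pars <- stats::setNames(misc$value, misc$param)
  pair_names <- c("AU", "CG", "GC", "UA", "GU", "UG")
  if (!identical(stack$pair, pair_names) ||
      !identical(names(stack)[-1], pair_names))
    stop("stack.tsv must be a 6x6 table over ", paste(pair_names, collapse = " "))
  sm <- as.matrix(stack[, -1])
  rownames(sm) <- pair_names
  wc <- c("AU", "UA", "GC", "CG")
  if (any(sm[wc, wc] >= 0))
    stop("Watson-Crick stacking energies must be negative")
  # symmetry of the duplex read from either strand: E[XY,WZ] == E[ZW,YX]
  flip <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (o in pair_names) for (i in pair_names)
    if (abs(sm[o, i] - sm[flip(i), flip(o)]) > 1e-9)
      stop("stacking table violates strand-flip symmetry at ", o, "/", i)
  model <- structure(list(stack = sm,
                          loops = loops,
                          ml_close = pars[["ml_close"]],
                          ml_branch = pars[["ml_branch"]],
                          ml_unpaired = pars[["ml_unpaired"]],
                          terminal_au = pars[["terminal_au"]],
                          ninio = pars[["ninio"]],
                          ninio_max = pars[["ninio_max"]],
                          lxc = pars[["lxc"]],
                          max_loop = as.integer(pars[["max_loop"]]),
                          min_hairpin = as.integer(pars[["min_hairpin"]])),
                     class = "energy_model")
  model$int <- .model_int_tables(model, max_length)
  model
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0("nearest-neighbor energy model (37 degC): %d pair types,",
                     " loop tables to %d nt (log-extrapolated),\n",
                     "  multibranch a=%.1f b=%.1f c=%.1f,",
                     " terminal AU/GU %.1f kcal/mol\n"),
              nrow(x$stack), length(x$int$hairpin), x$ml_close, x$ml_branch,
              x$ml_unpaired, x$terminal_au))
  invisible(x)
}

# integer-tenths tables extended to sequences of length n
.model_int_tables <- function(model, n) {
  n <- max(n, 31L)
  extend <- function(tab) {
    sizes <- model$loops$size
    v <- rep(NA_real_, n)
    v[sizes] <- tab
    last <- max(sizes[!is.na(tab)])
    if (n > last)
      v[(last + 1):n] <- v[last] + model$lxc * log(((last + 1):n) / last)
    iv <- as.integer(round(v * 10))
    iv[is.na(iv)] <- 10000000L  # impossible sizes; never reached by the DP
    iv
  }
  list(stack = matrix(as.integer(round(model$stack * 10)), 6, 6),
       hairpin = extend(model$loops$hairpin),
       bulge = extend(model$loops$bulge),
       internal = extend(model$loops$internal),
       ml_close = as.integer(round(model$ml_close * 10)),
       ml_branch = as.integer(round(model$ml_branch * 10)),
       ml_unpaired = as.integer(round(model$ml_unpaired * 10)),
       terminal_au = as.integer(round(model$terminal_au * 10)),
       ninio = as.integer(round(model$ninio * 10)),
       ninio_max = as.integer(round(model$ninio_max * 10)),
       max_loop = model$max_loop,
       min_hairpin = model$min_hairpin)
}

# parameter list for the C++ engine, guaranteed to cover length n
.model_params_int <- function(model, n) {
  if (length(model$int$hairpin) < n) model$int <- .model_int_tables(model, n)
  model$int
}

# lazily constructed package-default model
default_energy_model <- function() {
  if (is.null(.spacerfold_env$model))
    .spacerfold_env$model <- energy_model()
  .spacerfold_env$model
}

# base encoding for the engine: A=1 C=2 G=3 U=4, anything else 0 (never pairs)
encode_residues <- function(residues) {
  ch <- strsplit(residues, "")[[1]]
  codes <- match(ch, c("A", "C", "G", "U"))
  codes[is.na(codes)] <- 0L
  as.integer(codes)
}

PAIR_CODE <- local({
  m <- matrix(0L, 5, 5)
  m[2, 5] <- 1L; m[5, 2] <- 2L; m[4, 3] <- 3L; m[3, 4] <- 4L
  m[4, 5] <- 5L; m[5, 4] <- 6L
  m  # indexed by code+1
})

pair_type_of <- function(a, b) PAIR_CODE[cbind(a + 1L, b + 1L)]
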