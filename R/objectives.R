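#' Objective functions
#'
#' All objectives are minimized. Scores whose natural direction is
#' "higher is better" (QED, similarity) are complemented at registration.
#' Evaluations are cached by canonical SMILES; the unique-evaluation counter
#' increments on cache misses only and is what the optimizer's history
#' reports.
#'
#' @name objectives
NULL

new_objective <- function(name, fn, params = list()) {
  obj <- new.env(parent = emptyenv())
  obj$name <- name
  obj$fn <- fn
  obj$params <- params
  obj$cache <- new.env(parent = emptyenv())
  obj$n_evaluations <- 0L
  class(obj) <- "chem_objective"
  obj
}

#' @export
print.chem_objective <- function(x, ...) {
  cat(sprintf("<objective '%s'> %d unique evaluations\n", x$name, x$n_evaluations))
  invisible(x)
}

#' Evaluate an objective on a molecule
#'
#' @param spec a `chem_objective` from [objective()].
#' @param mol a `molecule` or SMILES string.
#' @return finite numeric value (lower is better).
#' @export
evaluate_objective <- function(spec, mol) {
  stopifnot(inherits(spec, "chem_objective"))
  mol <- canonicalize(mol)
  hit <- get0(mol$smiles, envir = spec$cache)
  if (!is.null(hit)) return(hit)
  v <- spec$fn(mol)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    stop(sprintf("objective '%s' returned a non-finite value for %s",
                 spec$name, mol$smiles))
  }
  spec$n_evaluations <- spec$n_evaluations + 1L
  assign(mol$smiles, v, envir = spec$cache)
  v
}

#' Number of unique molecules evaluated so far
#' @param spec a `chem_objective`.
#' @export
evaluation_count <- function(spec) spec$n_evaluations

#' Names of the built-in objectives
#' @return character vector.
#' @export
builtin_objectives <- function() c("sa", "qed", "logp", "simtarget", "external")

#' Construct an objective function
#'
#' Built-ins:
#' \describe{
#'   \item{sa}{synthetic accessibility score in `[1,10]`, minimized as-is.}
#'   \item{qed}{`1 - QED` (complemented so minimization maximizes
#'     drug-likeness).}
#'   \item{logp}{the additive logP surrogate, minimized as-is.}
#'   \item{simtarget}{Tanimoto distance to `target` (a SMILES); 0 at the
#'     target itself.}
#'   \item{external}{wraps `fun` (an R function of a molecule) or `cmd`
#'     (a program reading SMILES lines on stdin, writing one value per
#'     line).}
#' }
#'
#' @param name one of [builtin_objectives()].
#' @param target target SMILES for `simtarget`.
#' @param fun,cmd user callable / shell command for `external`.
#' @return a `chem_objective`.
#' @export
objective <- function(name, target = NULL, fun = NULL, cmd = NULL) {
  name <- match.arg(name, builtin_objectives())
  fn <- switch(name,
    sa = function(m) sa_score(m),
    qed = function(m) 1 - qed_score(m),
    logp = function(m) crippen_logp(m$graph),
    simtarget = {
      if (is.null(target)) stop("simtarget requires a `target` SMILES")
      tmol <- canonicalize(target)
      function(m) tanimoto_distance(m, tmol)
    },
    external = {
      if (is.null(fun) && is.null(cmd)) {
        stop("external requires `fun` or `cmd`")
      }
      if (!is.null(fun)) {
        function(m) as.numeric(fun(m))
      } else {
        function(m) {
          out <- system2(strsplit(cmd, " ")[[1]][1],
                         args = strsplit(cmd, " ")[[1]][-1],
                         input = m$smiles, stdout = TRUE)
          as.numeric(out[length(out)])
        }
      }
    }
  )
  new_objective(name, fn,
                params = list(target = target, cmd = cmd))
}
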