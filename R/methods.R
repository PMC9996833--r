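# ---------------------------------------------------------------------------
# S3 methods for fitted NOF objects
# ---------------------------------------------------------------------------

#' @export
print.nof_state <- function(x, ...) {
  cat(sprintf("%s solution (%s%s)\n", x$functional,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              if (is.null(x$history)) "" else
                sprintf(", %d outer iterations", nrow(x$history))))
  cat(sprintf("  E_total = %.9f hartree\n", x$energy$e_total))
  invisible(x)
}

#' @export
print.nof <- function(x, ...) {
  cat(sprintf("NOF fit: %s / %s, coupling %s (N_g = %d)\n", x$functional,
              x$basis_name, as.character(x$coupling), x$scheme$n_g))
  print(x$system)
  print.nof_state(x, ...)
  invisible(x)
}

#' @export
summary.nof <- function(object, ...) {
  md <- if (object$scheme$n_pairs > 0) m_diagnostic(object) else NULL
  out <- list(fit = object, energy = object$energy, m = md,
              trace = trace_check(object),
              occupations = coef(object))
  class(out) <- "summary.nof"
  out
}

#' @export
print.summary.nof <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$energy)
  if (!is.null(x$m)) {
    cat("\n")
    print(x$m)
  }
  cat(sprintf("\n1RDM trace: %.10f (N = %d, deviation %.2e)\n",
              x$trace$trace, x$trace$expected, x$trace$deviation))
  occ <- x$occupations
  show <- utils::head(order(-occ$occupation), 12)
  cat("\nLeading occupations (per spin):\n")
  print(occ[sort(show), ], row.names = FALSE)
  invisible(x)
}

#' Occupation numbers of a NOF fit
#'
#' @param object a fitted `nof` object.
#' @param ... unused.
#' @return data.frame with orbital index, region, subspace and per-spin
#'   occupation.
#' @export
coef.nof <- function(object, ...) {
  m <- object$scheme$n_coupled
  data.frame(orbital = seq_len(m),
             region = object$scheme$region[seq_len(m)],
             subspace = object$scheme$subspace[seq_len(m)],
             occupation = object$n)
}

#' Plot convergence and occupation spectrum of a NOF fit
#'
#' @param x a fitted `nof` object.
#' @param which `"history"` (outer-iteration energies) or `"occupations"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.nof <- function(x, which = c("history", "occupations"), ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    if (is.null(h) || nrow(h) == 0) stop("no history recorded")
    plot(h$iter, h$e_total, type = "b", xlab = "outer iteration",
         ylab = "E_total (hartree)",
         main = sprintf("%s convergence", x$functional), ...)
  } else {
    occ <- coef(x)
    plot(occ$orbital, occ$occupation, type = "h", xlab = "orbital",
         ylab = "n (per spin)", ylim = c(0, 1),
         main = sprintf("%s occupation spectrum", x$functional), ...)
    graphics::points(occ$orbital, occ$occupation, pch = 16)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# checkpoint / restart (plain JSON)
# ---------------------------------------------------------------------------

#' Checkpoint a NOF state to JSON
#'
#' Stores geometry, charge/multiplicity, basis, coupling, functional,
#' orbital coefficients and occupations; [nof_restore()] rebuilds integrals
#' and re-evaluates the energy.
#'
#' @param state a `nof_state`.
#' @param path output JSON path.
#' @export
nof_checkpoint <- function(state, path) {
  payload <- list(
    geometry = state$system$atoms,
    charge = state$system$charge,
    multiplicity = state$system$multiplicity,
    basis = state$basis_name %||% state$ao$basis_name,
    coupling = state$scheme$n_g,
    functional = state$functional,
    C = state$C,
    n = state$n)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Restore a checkpointed NOF state
#'
#' @param path JSON checkpoint from [nof_checkpoint()].
#' @return a `nof_state` with the stored orbitals/occupations and a freshly
#'   evaluated energy.
#' @export
nof_restore <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  system <- molecular_system(p$geometry, p$charge, p$multiplicity)
  ao <- ao_integrals(system, p$basis)
  scheme <- pairing_scheme(system, ao$n_basis, as.integer(p$coupling))
  new_nof_state(system, scheme, ao, matrix(unlist(p$C), ao$n_basis),
                as.numeric(p$n), p$functional)
}
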