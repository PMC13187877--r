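# Staged energy minimisation: steepest descent, then conjugate gradient,
# then L-BFGS, each with a step budget and an energy-change tolerance. The
# default schedule mirrors the common three-stage protocol (10,000 SD steps;
# up to 50,000 CG iterations to 1e-6 kcal/mol; up to 500,000 L-BFGS
# iterations to 1e-7 kcal/mol).

#' Default minimisation schedule
#'
#' @return list of stages, each `list(method, max_steps, tol)` with `tol` an
#'   energy-change-per-step threshold in kcal/mol
#' @export
default_min_schedule <- function() {
  list(list(method = "sd",    max_steps = 10000L,  tol = 1e-6),
       list(method = "cg",    max_steps = 50000L,  tol = 1e-6),
       list(method = "lbfgs", max_steps = 500000L, tol = 1e-7))
}

#' Minimise a structure under a harmonic potential model
#'
#' Runs the staged schedule and returns the relaxed structure together with a
#' `MinimizationReport` (per-stage method, steps used, energy change, and a
#' convergence flag verified by a final steepest-descent probe: the structure
#' is declared converged when one further descent step changes the energy by
#' no more than the last stage's tolerance).
#'
#' @param structure a [protein_structure()]
#' @param model a `PotentialModel`; an `enm` model keeps the spring topology
#'   of the input coordinates
#' @param schedule list of stages as in [default_min_schedule()]
#' @return list with elements `structure` (relaxed) and `report`
#' @export
minimize <- function(structure, model, schedule = default_min_schedule()) {
  xyz0 <- coords(structure)
  n <- nrow(xyz0)
  sp_model <- spring_model(model_springs(model, xyz0))  # freeze topology
  efun <- function(x) spring_energy(sp_model, matrix(x, n, 3))
  gfun <- function(x) as.vector(spring_gradient(sp_model, matrix(x, n, 3)))
  x <- as.vector(xyz0)
  stages <- list()
  for (st in schedule) {
    e0 <- efun(x)
    if (!is.finite(e0))
      stop("divergent energy entering stage '", st$method, "'")
    res <- switch(st$method,
      sd = .sd_minimize(efun, gfun, x, st$max_steps, st$tol),
      cg = {
        ctl <- list(maxit = st$max_steps,
                    reltol = st$tol / max(1, abs(e0)))
        o <- stats::optim(x, efun, gfun, method = "CG", control = ctl)
        list(x = o$par, steps = o$counts[["function"]])
      },
      lbfgs = {
        ctl <- list(maxit = st$max_steps,
                    factr = st$tol / .Machine$double.eps, pgtol = 0)
        o <- stats::optim(x, efun, gfun, method = "L-BFGS-B", control = ctl)
        list(x = o$par, steps = o$counts[["function"]])
      },
      stop("unknown minimisation method: ", st$method))
    e1 <- efun(res$x)
    if (!is.finite(e1))
      stop("divergent energy (NaN/Inf) in stage '", st$method, "'")
    x <- res$x
    stages[[length(stages) + 1L]] <-
      data.frame(method = st$method, steps = res$steps,
                 energy_change = e1 - e0, tol = st$tol)
  }
  # convergence probe: one more descent step must move energy < last tol
  last_tol <- schedule[[length(schedule)]]$tol
  probe <- .sd_minimize(efun, gfun, x, 1L, 0)
  de_probe <- abs(efun(probe$x) - efun(x))
  report <- structure(list(stages = do.call(rbind, stages),
                           final_energy = efun(x),
                           final_energy_change = de_probe,
                           tol = last_tol,
                           converged = de_probe <= last_tol),
                      class = "MinimizationReport")
  out <- structure
  out$atoms[, c("x", "y", "z")] <- matrix(x, n, 3)
  list(structure = out, report = report)
}

#' @export
print.MinimizationReport <- function(x, ...) {
  cat("<MinimizationReport>\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("final energy %.8g kcal/mol; probe dE %.3g; converged: %s\n",
              x$final_energy, x$final_energy_change, x$converged))
  invisible(x)
}

# steepest descent with backtracking line search; stops when the accepted
# energy decrease falls below tol or the gradient vanishes
.sd_minimize <- function(efun, gfun, x, max_steps, tol) {
  e <- efun(x)
  alpha <- 1e-3
  steps <- 0L
  while (steps < max_steps) {
    g <- gfun(x)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    accepted <- FALSE
    for (try in 1:40) {
      xn <- x - alpha * g
      en <- efun(xn)
      if (is.finite(en) && en < e) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break
    de <- e - en
    x <- xn; e <- en; steps <- steps + 1L
    alpha <- alpha * 1.5
    if (de < tol) break
  }
  list(x = x, steps = steps)
}
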