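# Independent oracles used across the suite. These deliberately avoid the
# package's own root/mapping helpers: roots come from polyroot(), bound
# concentrations from uniroot() on the raw mass-balance equations.

nM <- 1e-9
uM <- 1e-6

# roots of the equilibrium binding quadratic via polyroot
oracle_roots <- function(Et, It, ki) {
  r <- sort(Re(polyroot(c(Et * It, -(Et + It + ki), 1))))
  list(x1 = r[1], x2 = r[2])
}

# map mechanistic truth to observable (v0, vs, k, gamma) via the oracle roots
oracle_observables <- function(kon, koff, Et, It, v0_abs) {
  r <- oracle_roots(Et, It, koff / kon)
  list(v0 = v0_abs, vs = v0_abs * (Et - r$x1) / Et,
       k = kon * (r$x2 - r$x1), gamma = r$x1 / r$x2)
}

# bound titrant concentration from raw mass balance: (X-B)(nM-B)/B = kd
oracle_bound <- function(n, kd, Mt, Xt) {
  if (Xt == 0) return(0)
  f <- function(B) (Xt - B) * (n * Mt - B) - kd * B
  stats::uniroot(f, c(0, min(Xt, n * Mt)), tol = 1e-18)$root
}

# synthetic exact progress_fit objects from Morrison steady states
morrison_fits <- function(Et, ki, its, v0 = 1) {
  lapply(its, function(It) {
    fr <- morrison_fraction(Et, It, ki)
    structure(list(curve_id = sprintf("It%g", It), inhibitor_conc = It,
                   Et = Et, v0 = v0, vs = fr * v0, k = 1, A0 = 0,
                   gamma = gamma_of(Et, It, v0, fr * v0),
                   converged = TRUE, k_identifiable = TRUE),
              class = "progress_fit")
  })
}
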