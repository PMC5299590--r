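# Shared fixtures, memoized so expensive constructions (optimizations,
# QHA states) run once per test session.

.memo <- new.env(parent = emptyenv())
memo <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

fx_chain <- function() memo("chain", chain_1d())
fx_fcc <- function() memo("fcc", exp6_fcc())
fx_dia <- function(p) {
  memo(paste0("dia_", p), rigid_diatomic_crystal(packing = p))
}

# all fixtures as a named list (for "on every fixture" properties)
fx_all <- function() {
  list(chain = fx_chain(), fcc = fx_fcc(),
       dia_alpha = fx_dia("alpha"), dia_beta = fx_dia("beta"))
}

# quasi-harmonic states of the fcc fixture with the full (ZPE-inclusive)
# thermal pressure, shared between the QHA-oracle and softening tests
fx_fcc_qha <- function(T) {
  memo(paste0("fcc_qha_", T), {
    fx <- fx_fcc()
    qha_state(fx$crystal, fx$ff, T, zpe_pressure = TRUE)
  })
}

# independent direct-summation (Evjen) oracle for the Madelung constant of
# the rock-salt lattice: charge-weighted sum over an expanding cube with
# fractional weights on faces, edges and corners
evjen_madelung_nacl <- function(nmax = 8) {
  idx <- -nmax:nmax
  g <- expand.grid(i = idx, j = idx, k = idx)
  g <- g[!(g$i == 0 & g$j == 0 & g$k == 0), ]
  w <- function(v) ifelse(abs(v) == nmax, 0.5, 1)
  wt <- w(g$i) * w(g$j) * w(g$k)
  q <- (-1)^(abs(g$i) + abs(g$j) + abs(g$k))
  r <- sqrt(g$i^2 + g$j^2 + g$k^2)
  -sum(wt * q / r)
}

# brute-force rotation-grid lower bound for the superposition RMSD
rmsd_rotation_grid <- function(X, Y, nang = 24) {
  X <- sweep(X, 2, colMeans(X)); Y <- sweep(Y, 2, colMeans(Y))
  best <- Inf
  angs <- seq(0, 2 * pi, length.out = nang + 1)[-(nang + 1)]
  half <- seq(0, pi, length.out = nang / 2 + 1)
  for (a in angs) for (b in half) for (c in angs) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    R <- Rz1 %*% Ry %*% Rz2
    v <- sqrt(mean(rowSums((X - Y %*% R)^2)))
    if (v < best) best <- v
  }
  best
}

# frequencies (cm^-1) from a dynamical matrix
dyn_freqs <- function(Dm) {
  lam <- eigen(Dm, symmetric = TRUE, only.values = TRUE)$values
  sort(sign(lam) * physical_constants()$freq_to_cm1 * sqrt(abs(lam)))
}

# path to the thermal-expansion benchmark table shipped with the package
alpha_v_table <- function() {
  read.csv(system.file("extdata", "alpha_v_benchmark.csv",
                       package = "polyphonon"))
}
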