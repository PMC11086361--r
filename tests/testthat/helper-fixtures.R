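## Memoized fixtures shared across test files (built once per test run).
.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build
  .fx[[name]]
}

## Highly focused chain (reference conditions): WL = 35.9 um, z0 = 252 um,
## lambda0 = 0.85 um, seven scatterers 24-480 um.
focused_config <- function() fx("foccfg", config_focused_chain())
focused_scene <- function() chain_scene()
focused_volume <- function() fx("focvol", simulate_volume(focused_scene(), focused_config()))
focused_refocused <- function() fx("focref", refocus_one_step(focused_volume()))

## Weakly focused pair chain (W0 = 12.6 um, pairs 12 um apart).
pairs_config <- function() fx("paircfg", config_weak_pairs())
pairs_scene <- function() pair_chain_scene()
pairs_volume <- function() fx("pairvol", simulate_volume(pairs_scene(), pairs_config()))

## Aberrated chain (coma Z_3^1, 60 rad) and its aberration-free twin,
## at the 128-sample lateral grid used for the correction experiments.
ab_config <- function() fx("abcfg", config_aberrated_chain(n_x = 128))
free_config <- function() {
  fx("freecfg", config_focused_chain(n_x = 128, propagator_mode = "full"))
}
ab_volume <- function() fx("abvol", simulate_volume(chain_scene(), ab_config()))
free_volume <- function() fx("freevol", simulate_volume(chain_scene(), free_config()))

## ad-hoc scene from coordinate vectors
scene_at <- function(xs, ys = 0, zs, Ks = 1 + 0i) {
  tibble::tibble(xs = xs, ys = rep_len(ys, length(xs)),
                 zs = rep_len(zs, length(xs)), Ks = rep_len(Ks, length(xs)))
}

## small complex random matrix
rand_cplx <- function(n, m = n) {
  matrix(complex(real = stats::rnorm(n * m), imaginary = stats::rnorm(n * m)), n, m)
}

## relative RMS difference of two arrays
rel_rms <- function(a, b) sqrt(mean(abs(a - b)^2)) / sqrt(mean(abs(b)^2))

## max deviation between peak-normalized en-face amplitude images at depth z
slice_dev <- function(va, vb, z) {
  qa <- which.min(abs(va$depth$z - z))
  qb <- which.min(abs(vb$depth$z - z))
  a <- abs(va$A[, , qa]); b <- abs(vb$A[, , qb])
  max(abs(a / max(a) - b / max(b)))
}
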