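# Shared fixtures, built once per test run. The "small" cohort is a
# scaled-down version of the default phantom (32^3 grid, 6 NC / 8 MCI)
# so module tests stay fast; the acceptance file builds the full-size
# default cohort itself.

.fixtures <- new.env(parent = emptyenv())

small_profile <- function(...) {
  args <- utils::modifyList(
    list(n_nc = 6L, n_mci = 8L, grid_shape = c(32L, 32L, 32L),
         seed = 42L), list(...))
  do.call(simulation_profile, args)
}

# ladder capped so max sigma < 32/3
small_ladder <- function() scale_ladder(n_scales = 8L)

small_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulate_cohort(small_profile())
  .fixtures$sim
}

small_features <- function() {
  if (is.null(.fixtures$feat)) {
    sim <- small_sim()
    .fixtures$feat <- cohort_feature_table(sim$cohort, sim$atlas,
                                           sim$registry,
                                           ladder = small_ladder())
  }
  .fixtures$feat
}

# full-size default cohort (84 subjects, 64^3, seed 42): the acceptance
# fixture, also used by the permutation-null property test
acceptance_sim <- function() {
  if (is.null(.fixtures$acc_sim))
    .fixtures$acc_sim <- simulate_cohort(simulation_profile())
  .fixtures$acc_sim
}

acceptance_features <- function() {
  if (is.null(.fixtures$acc_feat)) {
    sim <- acceptance_sim()
    .fixtures$acc_feat <- cohort_feature_table(sim$cohort, sim$atlas,
                                               sim$registry)
  }
  .fixtures$acc_feat
}

planted_region_ids <- function(registry) {
  sort(match(simulation_profile()$affected_regions, registry$name))
}

# tiny label volume for parcellation unit tests: 8^3 grid, two labels
tiny_atlas <- function() {
  lab <- array(0L, dim = c(8, 8, 8))
  lab[2:4, 2:4, 2:4] <- 1L
  lab[6:7, 6:7, 6:7] <- 2L
  label_volume(lab, vol_grid(c(8, 8, 8)))
}

# a volume on the tiny atlas grid with the given constant value
tiny_volume <- function(value = 1) {
  pet_volume(array(value, dim = c(8, 8, 8)), vol_grid(c(8, 8, 8)))
}

# Gaussian bump helper: amplitude * exp(-|r - c|^2 / (2 s0^2))
add_bump <- function(arr, center, sigma0, amplitude) {
  d <- dim(arr)
  dx2 <- (seq_len(d[1]) - center[1])^2
  dy2 <- (seq_len(d[2]) - center[2])^2
  dz2 <- (seq_len(d[3]) - center[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  arr + amplitude * exp(-r2 / (2 * sigma0^2))
}
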