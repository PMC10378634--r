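# shared fixtures; everything is built in code at test time

# tiny single-beam phantom for dose-model and DVH tests
tiny_phantom <- function(shape = c(20L, 20L, 20L), spacing = c(2, 2, 2)) {
  build_phantom(list(
    grid = list(shape = shape, spacing = spacing),
    primary = list(name = "T", center = c(0, 0, 0), radii = c(8, 8, 8),
                   prescription_Gy = 60)))
}

tiny_beam <- function(weight = 1, lateral_sigma_mm = 12) {
  beam_spec(c(1, 0, 0), c(0, 0, 0), nominal_range_mm = 50, modulation_mm = 30,
            lateral_sigma_mm = lateral_sigma_mm, falloff_sigma_mm = 2,
            weight = weight)
}

# a 4-patient, 2-fraction miniature cohort config for pipeline tests
mini_config <- function(seed = 42L) {
  cfg <- default_cohort_config(seed)
  pat <- function(id, class, n) list(
    id = id, class = class, n_fractions = n,
    shift = list(sd_trans_mm = if (class == "PO") 2.8 else 1.7,
                 sd_rot_deg = if (class == "PO") 2.0 else 1.2))
  cfg$patients <- list(pat("A", "PO", 2L), pat("B", "PO", 2L),
                       pat("C", "PNN", 2L), pat("D", "PNN", 2L))
  cfg
}

# memoized default-cohort run shared by the acceptance tests
.rtrobust_cache <- new.env(parent = emptyenv())
get_default_run <- function() {
  if (is.null(.rtrobust_cache$run))
    .rtrobust_cache$run <- run_cohort(default_cohort_config(), outdir = NULL,
                                      figures = FALSE)
  .rtrobust_cache$run
}
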