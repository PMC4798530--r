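# Shared fixtures, built in code at test time.

# One-type parameter set with CAP fixed at the national average density.
ref_params <- function(cap = 114, t99 = 40, root_shoot = 0,
                       degraded_equiv_age = 25, constants = global_constants()) {
  ft <- data.frame(name = "humid", share = 1, median_biomass = 2 * cap,
                   t99 = t99, root_shoot = root_shoot,
                   stringsAsFactors = FALSE)
  build_params(config = list(forest_types = ft,
                             cap_override = c(humid = cap),
                             degraded_equiv_age = degraded_equiv_age),
               constants = constants)
}

ref_type <- function(...) {
  p <- ref_params(...)
  as.list(p$types[1, ])
}

make_pixel <- function(cover_1990, cover_2000, cover_2010,
                       forest_type = "humid", area_ha = 10000,
                       soc_ref = 100, biomass = 228,
                       department = "dept_a", municipality = "muni_a",
                       pixel_id = "px1") {
  data.frame(pixel_id = pixel_id, area_ha = area_ha,
             forest_type = forest_type, agb_biomass_t_ha = biomass,
             soc_ref = soc_ref, department = department,
             municipality = municipality,
             cover_1990 = cover_1990, cover_2000 = cover_2000,
             cover_2010 = cover_2010, stringsAsFactors = FALSE)
}

small_landscape <- function(n = 300, seed = 42) {
  gen_landscape(gen_national_like(n_pixels = n, seed = seed))
}
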