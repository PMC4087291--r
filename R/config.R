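#' Run configuration
#'
#' All tunable settings of the simulate/reconstruct/render/validate
#' workflows live in one nested key/value configuration, stored as YAML.
#' [default_run_config()] returns the built-in defaults (100 cm SSD,
#' 10 x 10 cm field, 50 x 30 cm phantom section, 0.1 cm reconstruction
#' pixels, the 0.5 cm scoring layout for simulation, the default beam
#' model, decile band edges, the standard palette and the 2%/5%
#' in-field/penumbra validation bounds). [read_run_config()] reads a YAML
#' file and fills every unset key from the defaults.
#'
#' @param path YAML file path.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  cfg <- list(
    geometry = list(ssd_cm = 100, field_cm = 10,
                    phantom_halfwidth_cm = 25, phantom_depth_cm = 30),
    grid = list(pixel_cm = 0.1, lateral_halfwidth_cm = 15, depth_cm = 28),
    scoring = list(voxel_cm = 0.5, n_depth = 56, n_lateral = 60),
    beam_model = list(mu_per_cm = 0.045, d_max_cm = 3.25,
                      penumbra_sigma0_cm = 0.3, penumbra_growth = 0.04,
                      tail_amplitude_pct = 2, tail_decay_cm = 5,
                      truth = "separable"),
    bands = list(edges_pct = c(1, seq(10, 100, by = 10))),
    palette = lapply(seq_len(nrow(default_palette())), function(k) {
      p <- default_palette()[k, ]
      list(lo = p$lo, hi = p$hi, name = p$name, hue = p$hue, sat = p$sat)
    }),
    validation = list(in_field_max_pct = 2, penumbra_max_pct = 5),
    seed = 1L
  )
  structure(cfg, class = "run_config")
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(default_run_config()), user)
  structure(cfg, class = "run_config")
}

merge_config <- function(base, user) {
  if (!is.list(user)) return(user)
  if (!is.list(base) || is.null(names(base))) return(user)
  for (k in names(user)) base[[k]] <- merge_config(base[[k]], user[[k]])
  base
}

#' @rdname default_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---- materialise package objects from a config -----------------------------

config_geometry <- function(cfg) {
  g <- cfg$geometry
  beam_geometry(ssd = g$ssd_cm, field_size = g$field_cm,
                phantom_halfwidth = g$phantom_halfwidth_cm,
                phantom_depth = g$phantom_depth_cm)
}

config_grid <- function(cfg, geom = config_geometry(cfg)) {
  g <- cfg$grid
  symmetric_grid(g$pixel_cm, halfwidth = g$lateral_halfwidth_cm,
                 depth = g$depth_cm, geom = geom)
}

config_scoring_grid <- function(cfg) {
  s <- cfg$scoring
  scoring_grid(voxel_side = s$voxel_cm, n_depth = s$n_depth,
               n_lateral = s$n_lateral)
}

config_params <- function(cfg) {
  b <- cfg$beam_model
  beam_model_params(mu = b$mu_per_cm, d_max_target = b$d_max_cm,
                    penumbra_sigma0 = b$penumbra_sigma0_cm,
                    penumbra_growth = b$penumbra_growth,
                    tail_amplitude = b$tail_amplitude_pct,
                    tail_decay = b$tail_decay_cm)
}

config_palette <- function(cfg) {
  dplyr::bind_rows(lapply(cfg$palette, tibble::as_tibble))
}
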