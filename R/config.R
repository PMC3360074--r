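# Default experiment configuration and stimulus serialization.
#
# The default design crosses 6 association-field jitter pairs with 7 contour
# lengths. Total contour extent is held approximately constant (14.4 DVA), so
# the mean inter-edge distance is 14.4 / L and spans 1.2 to 3.6 DVA across
# lengths 12 down to 4. Each of the 42 ensembles contains 48 stimuli (24
# targets per hemifield), giving 2016 stimuli per observer and SOA. The
# specific jitter values and length grid are package defaults chosen to span
# straight/aligned to curved/jittered contours; they are reconstructions, not
# published values.

#' Default experiment configuration
#'
#' @param seed Master seed stored in the configuration.
#' @param n_stimuli Stimuli per ensemble.
#' @param field_width,field_height Field extent, DVA.
#' @return A list of class `af_config` with elements `af_sets` (6 jitter
#'   pairs), `lengths` (7 contour lengths), `ensembles` (42-row tibble with
#'   `ensemble_id`, `sigma_align`, `sigma_curv`, `L`, `spacing`), `soas`,
#'   `eps_max`, `v` (propagation speed), field geometry and `seed`.
#' @examples
#' cfg <- default_experiment_config()
#' nrow(cfg$ensembles)
#' @export
default_experiment_config <- function(seed = 1L, n_stimuli = 48L,
                                      field_width = 26.6, field_height = 20) {
  af_sets <- tibble(
    af_set = sprintf("af%d", 1:6),
    sigma_align = c(4, 8, 8, 16, 16, 32) * pi / 180,
    sigma_curv = c(8, 8, 16, 16, 32, 32) * pi / 180
  )
  lengths <- c(4L, 5L, 6L, 7L, 8L, 10L, 12L)
  contour_extent <- 14.4
  ensembles <- tidyr::expand_grid(af_sets, L = lengths) %>%
    mutate(spacing = contour_extent / .data$L,
           ensemble_id = sprintf("%s_L%02d", .data$af_set, .data$L))
  structure(
    list(af_sets = af_sets, lengths = lengths, ensembles = ensembles,
         n_stimuli = as.integer(n_stimuli),
         soas = c(20, 30, 60, 100, 200),
         eps_max = 16.66, v = 13.9 / 200,
         field_width = field_width, field_height = field_height,
         min_separation = 0.46, contour_extent = contour_extent,
         seed = as.integer(seed)),
    class = "af_config"
  )
}

#' @export
print.af_config <- function(x, ...) {
  cat(sprintf(
    "<af_config> %d ensembles (%d AF sets x %d lengths), %d stimuli each (%d per session), SOAs {%s} ms\n",
    nrow(x$ensembles), nrow(x$af_sets), length(x$lengths), x$n_stimuli,
    nrow(x$ensembles) * x$n_stimuli, paste(x$soas, collapse = ", ")))
  invisible(x)
}

#' Ensemble specifications of a configuration
#'
#' Expands an [default_experiment_config()] object into a list of
#' [ensemble_spec()] objects. The generating association field of each
#' ensemble uses the condition's jitter pair and sets its radial scale to the
#' condition's mean inter-edge distance.
#'
#' @param config An `af_config` object.
#' @return A named list of `ensemble_spec` objects.
#' @export
ensemble_specs <- function(config) {
  stopifnot(inherits(config, "af_config"))
  specs <- purrr::pmap(config$ensembles, function(af_set, sigma_align,
                                                  sigma_curv, L, spacing,
                                                  ensemble_id) {
    ensemble_spec(
      af = af_params(sigma_align, sigma_curv, lambda_radial = spacing),
      L = L, n_stimuli = config$n_stimuli,
      field_width = config$field_width, field_height = config$field_height,
      spacing = spacing, min_separation = config$min_separation,
      ensemble_id = ensemble_id
    )
  })
  stats::setNames(specs, config$ensembles$ensemble_id)
}

spec_table <- function(specs) {
  purrr::map(specs, function(s) {
    tibble(ensemble_id = s$ensemble_id, L = s$L, spacing = s$spacing,
           sigma_align = s$af$sigma_align, sigma_curv = s$af$sigma_curv,
           lambda_radial = s$af$lambda_radial, n_stimuli = s$n_stimuli)
  }) %>% bind_rows()
}

#' Write / read stimuli as CSV with a JSON sidecar
#'
#' One row per edge (`stimulus_id, ensemble_id, target_side, hemifield, role,
#' contour_order, x_dva, y_dva, theta_rad, theta_mask_rad`), plus a JSON
#' sidecar (`<path>.json`) carrying the ensemble specification and seed.
#'
#' @param stimuli A stimulus tibble.
#' @param path CSV path.
#' @param seed Seed recorded in the sidecar.
#' @return `read_stimuli()` returns the stimulus tibble with its
#'   `"ensemble_spec"` attribute restored (when the sidecar is present).
#' @export
write_stimuli <- function(stimuli, path, seed = NULL) {
  out <- stimuli %>%
    rename(x_dva = "x", y_dva = "y", theta_rad = "theta",
           theta_mask_rad = "theta_mask")
  readr::write_csv(out, path)
  sp <- attr(stimuli, "ensemble_spec")
  if (!is.null(sp)) {
    side <- list(
      ensemble_id = sp$ensemble_id, L = sp$L, n_stimuli = sp$n_stimuli,
      field_width = sp$field_width, field_height = sp$field_height,
      spacing = sp$spacing, min_separation = sp$min_separation,
      af = af_to_list(sp$af), seed = seed
    )
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE) %>%
    rename(x = "x_dva", y = "y_dva", theta = "theta_rad",
           theta_mask = "theta_mask_rad")
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(tbl, "ensemble_spec") <- ensemble_spec(
      af = af_from_list(side$af), L = side$L, n_stimuli = side$n_stimuli,
      field_width = side$field_width, field_height = side$field_height,
      spacing = side$spacing, min_separation = side$min_separation,
      ensemble_id = side$ensemble_id
    )
  }
  tbl
}
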