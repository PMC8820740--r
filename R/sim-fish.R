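#' Generate a synthetic smFISH field
#'
#' Simulates one imaged field of the CA1 region: a curved cell-body-layer
#' boundary y = f(x) (polynomial, µm), nuclei filling a band on the cell-body
#' side of the boundary (emitted as a pixel mask), and FISH spots drawn from
#' a two-component mixture — a cell-body component uniform within the layer
#' and a neuropil component whose density decays exponentially with distance
#' from the boundary. The cell-body side is low y; the neuropil side is high
#' y. Per-spot ground truth (mixture component and signed vertical distance
#' to the true boundary) is recorded.
#'
#' @param cfg a [sim_config()] object; `fish_boundary_coeffs` must keep the
#'   curve inside the image frame.
#' @param image_id label stored with the spots.
#' @return a list of class `fish_field`: `spots` (x_um, y_um, z_um, channel,
#'   image_id), `nuclei_px` (row, col pixel list), `um_per_px`,
#'   `boundary_coeffs`, `cb_side`, and `truth` (per-spot component and true
#'   signed distance).
#' @export
gen_fish_field <- function(cfg, image_id = "img1") {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed + 3000L)

  W <- cfg$fish_width_um
  f <- function(x) poly_eval(cfg$fish_boundary_coeffs, x)

  # nuclei: discs of radius ~3 um filling the cell-body band; the boundary
  # runs through the centres of the outermost nuclei, so discs straddle it
  r_nuc <- 3
  nx <- runif(cfg$fish_n_nuclei, 0, W)
  ny <- f(nx) - runif(cfg$fish_n_nuclei, 0, cfg$fish_layer_um - r_nuc)
  px <- cfg$um_per_px
  nuclei_px <- do.call(rbind, lapply(seq_along(nx), function(i) {
    cc <- round(nx[i] / px); rc <- round(ny[i] / px); rr <- round(r_nuc / px)
    d <- expand.grid(col = (cc - rr):(cc + rr), row = (rc - rr):(rc + rr))
    d <- d[(d$col - cc)^2 + (d$row - rc)^2 <= rr^2, ]
    d
  }))
  nuclei_px <- unique(nuclei_px[nuclei_px$row >= 0 & nuclei_px$col >= 0, ])

  # spots: mixture of cell-body and neuropil components
  n <- cfg$fish_n_spots
  in_np <- runif(n) < cfg$fish_neuropil_weight
  sx <- runif(n, 0, W)
  d_true <- numeric(n)
  d_true[in_np] <- rexp(sum(in_np), rate = 1 / cfg$fish_decay_um)
  d_true[!in_np] <- -runif(sum(!in_np), 0, cfg$fish_layer_um)
  sy <- f(sx) + d_true
  sx <- sx + rnorm(n, 0, cfg$spot_noise_sd)
  sy <- sy + rnorm(n, 0, cfg$spot_noise_sd)

  spots <- data.frame(
    spot_id = sprintf("s%05d", seq_len(n)),
    x_um = sx, y_um = sy, z_um = runif(n, 0, 5),
    channel = "probe", image_id = image_id, stringsAsFactors = FALSE)
  truth <- data.frame(
    spot_id = spots$spot_id,
    component = ifelse(in_np, "neuropil", "cell-body"),
    true_distance = d_true, stringsAsFactors = FALSE)

  structure(list(spots = spots, nuclei_px = nuclei_px, um_per_px = px,
                 boundary_coeffs = cfg$fish_boundary_coeffs,
                 cb_side = "low", truth = truth),
            class = "fish_field")
}
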