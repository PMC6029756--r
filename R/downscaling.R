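# Bias-correction spatial disaggregation (BCSD): monthly quantile bias maps
# fitted between coarse model output and coarse gridded observations,
# quantile-position bias removal (historical biases assumed to persist in
# the future), and additive anomaly disaggregation to the fine grid with
# bilinear interpolation guided by observed monthly climatologies.

#' Fit monthly quantile bias maps
#'
#' For every coarse cell and calendar month, all daily values across the
#' years of the historical period are pooled (month-matched, not
#' day-matched), and empirical quantiles of the model and observation pools
#' are taken at K equally spaced probability points `q_k = k / (K + 1)`.
#' The bias at each point is `Q_M(q) - Q_O(q)`.
#'
#' @param model_hist Coarse daily grid-field tibble (historical model run).
#' @param obs Coarse daily grid-field tibble of gridded observations over
#'   the same period; cell-months with no observations are marked unusable
#'   and excluded downstream.
#' @param K Number of probability points (default 99).
#' @return An `oz_bias_maps` tibble `cell_id, month, q, q_model, q_obs,
#'   bias`, with unusable cell-months in attribute `"unusable"`.
#' @export
fit_monthly_quantile_bias <- function(model_hist, obs, K = 99) {
  stopifnot(K >= 2)
  qgrid <- seq_len(K) / (K + 1)
  pool <- function(fld) {
    as_tibble(fld)[, c("cell_id", "date", "value")] %>%
      filter(!is.na(.data$value)) %>%
      mutate(month = lubridate::month(.data$date))
  }
  mp <- pool(model_hist)
  op <- pool(obs)
  keys <- distinct(mp[, c("cell_id", "month")])

  res <- purrr::pmap(keys, function(cell_id, month) {
    mv <- mp$value[mp$cell_id == cell_id & mp$month == month]
    ov <- op$value[op$cell_id == cell_id & op$month == month]
    if (length(ov) == 0 || length(mv) == 0) return(NULL)
    if (length(ov) < K / 2 || length(mv) < K / 2) {
      warn(sprintf("cell %s month %d: pool smaller than K/2 (%d model, %d obs)",
                   cell_id, month, length(mv), length(ov)))
    }
    qm <- unname(quantile(mv, qgrid, type = 7))
    qo <- unname(quantile(ov, qgrid, type = 7))
    tibble(cell_id = cell_id, month = month, q = qgrid,
           q_model = qm, q_obs = qo, bias = qm - qo)
  })
  maps <- bind_rows(res)
  usable <- distinct(maps[, c("cell_id", "month")])
  unusable <- anti_join(keys, usable, by = c("cell_id", "month"))
  structure(maps, K = K, unusable = unusable,
            class = c("oz_bias_maps", class(maps)))
}

#' Quantile-position bias correction of a coarse daily field
#'
#' Each daily value `x` in cell g, month m is placed on the historical
#' model CDF of (g, m) — the probability position `q*` is read off the
#' fitted model quantiles by linear interpolation, constant beyond the
#' outer points — and the monthly bias at that position is subtracted:
#' `x' = x - b(q*)`. Placing future values on the *historical* model CDF
#' encodes the assumption that historical monthly biases persist in the
#' future. Results are clamped at 0 ppb. Values in cells whose map is
#' unusable become missing.
#'
#' @param field Coarse daily grid-field tibble (historical or future).
#' @param maps An `oz_bias_maps` object from [fit_monthly_quantile_bias()].
#' @return Corrected grid-field tibble of the same shape.
#' @export
bias_correct_daily <- function(field, maps) {
  grid <- field_grid(field)
  df <- as_tibble(field)[, c("cell_id", "date", "value")] %>%
    mutate(month = lubridate::month(.data$date))
  mapl <- split(as_tibble(maps), paste(maps$cell_id, maps$month))
  out <- df %>%
    group_by(.data$cell_id, .data$month) %>%
    group_modify(function(d, k) {
      m <- mapl[[paste(k$cell_id, k$month)]]
      if (is.null(m)) {
        d$value <- NA_real_
        return(d)
      }
      x <- d$value
      qstar <- if (diff(range(m$q_model)) < 1e-12) {
        rep(0.5, length(x))
      } else {
        approx(m$q_model, m$q, xout = x, rule = 2, ties = mean)$y
      }
      b <- approx(m$q, m$bias, xout = qstar, rule = 2)$y
      d$value <- ifelse(is.na(x), NA_real_, pmax(x - b, 0))
      d
    }) %>%
    ungroup() %>%
    select("cell_id", "date", "value") %>%
    arrange(.data$cell_id, .data$date)
  new_grid_field(out, grid)
}

#' Spatial disaggregation of a bias-corrected coarse field
#'
#' The additive temporal scaling factor (anomaly) of each coarse cell is the
#' corrected daily value minus the coarse observed monthly climatology. The
#' anomaly field is bilinearly interpolated from coarse cell centers to fine
#' cell centers (constant extrapolation beyond the outermost centers), and
#' the fine observed monthly climatology is added back. Output is clamped
#' at 0 ppb.
#'
#' @param corrected Coarse daily grid-field tibble (bias-corrected).
#' @param obs_clim_coarse,obs_clim_fine Monthly climatologies from
#'   [monthly_climatology()] on the coarse and fine grids (all needed
#'   months present).
#' @param fine_cells Optional character vector restricting output to a
#'   subset of fine cells (e.g. only cells belonging to cities).
#' @return Fine daily grid-field tibble.
#' @export
spatial_disaggregate_daily <- function(corrected, obs_clim_coarse,
                                       obs_clim_fine, fine_cells = NULL) {
  coarse <- field_grid(corrected)
  fine <- field_grid(obs_clim_fine)
  ccells <- grid_cells(coarse)
  fcells <- grid_cells(fine)
  if (!is.null(fine_cells)) {
    fcells <- fcells[fcells$cell_id %in% fine_cells, ]
  }
  dates <- sort(unique(corrected$date))
  months <- lubridate::month(dates)
  need <- sort(unique(months))
  have <- sort(unique(obs_clim_coarse$month))
  if (!all(need %in% have) || !all(need %in% unique(obs_clim_fine$month))) {
    abort("climatologies must cover all months present in the field")
  }

  # coarse anomaly matrix: cells x dates
  V <- matrix(NA_real_, nrow(ccells), length(dates),
              dimnames = list(ccells$cell_id, NULL))
  cf <- as_tibble(corrected)
  V[cbind(match(cf$cell_id, ccells$cell_id), match(cf$date, dates))] <- cf$value
  CC <- matrix(NA_real_, nrow(ccells), 12)
  occ <- as_tibble(obs_clim_coarse)
  CC[cbind(match(occ$cell_id, ccells$cell_id), occ$month)] <- occ$value
  S <- V - CC[, months, drop = FALSE]

  W <- bilinear_weight_matrix(coarse, fcells$lat, fcells$lon)
  Sf <- interp_with_na(W, S)
  if (is.null(dim(Sf))) Sf <- matrix(Sf, nrow = nrow(fcells))

  FC <- matrix(NA_real_, nrow(fcells), 12)
  ocf <- as_tibble(obs_clim_fine)
  ocf <- ocf[ocf$cell_id %in% fcells$cell_id, ]
  FC[cbind(match(ocf$cell_id, fcells$cell_id), ocf$month)] <- ocf$value
  out <- pmax(Sf + FC[, months, drop = FALSE], 0)

  fld <- tibble(
    cell_id = rep(fcells$cell_id, times = length(dates)),
    date = rep(dates, each = nrow(fcells)),
    value = as.vector(out)
  )
  new_grid_field(fld, fine)
}

#' Run the full BCSD chain for one scenario and ensemble member
#'
#' Fits the monthly quantile bias maps on the historical pair, corrects the
#' historical and future model fields, and disaggregates both to the fine
#' grid. Emits per-stage diagnostics: domain-mean bias against the gridded
#' observations before and after correction, and the per-month RMSE between
#' the corrected historical quantiles and the observed quantiles.
#'
#' @param model_hist,model_fut Coarse daily model grid-field tibbles.
#' @param obs_coarse Coarse daily gridded observations (historical period).
#' @param obs_clim_coarse,obs_clim_fine Observed monthly climatologies.
#' @param K Number of quantile points (default 99).
#' @param fine_cells Optional fine-cell subset for the disaggregation.
#' @return An `oz_downscale` list: `hist_fine`, `fut_fine`,
#'   `hist_corrected`, `fut_corrected`, `bias_maps`, `diagnostics`.
#' @export
downscale <- function(model_hist, model_fut, obs_coarse,
                      obs_clim_coarse, obs_clim_fine,
                      K = 99, fine_cells = NULL) {
  maps <- fit_monthly_quantile_bias(model_hist, obs_coarse, K = K)
  hist_corr <- bias_correct_daily(model_hist, maps)
  fut_corr <- bias_correct_daily(model_fut, maps)
  hist_fine <- spatial_disaggregate_daily(hist_corr, obs_clim_coarse,
                                          obs_clim_fine, fine_cells)
  fut_fine <- spatial_disaggregate_daily(fut_corr, obs_clim_coarse,
                                         obs_clim_fine, fine_cells)

  mean_bias <- function(fld) {
    j <- inner_join(as_tibble(fld)[, c("cell_id", "date", "value")],
                    as_tibble(obs_coarse)[, c("cell_id", "date", "value")],
                    by = c("cell_id", "date"), suffix = c("", "_obs"))
    mean(j$value - j$value_obs, na.rm = TRUE)
  }
  qgrid <- seq_len(attr(maps, "K")) / (attr(maps, "K") + 1)
  corr_q <- as_tibble(hist_corr) %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$cell_id, month = lubridate::month(.data$date)) %>%
    dplyr::reframe(q = qgrid,
                   q_corr = unname(quantile(.data$value, qgrid, type = 7)))
  month_rmse <- corr_q %>%
    inner_join(as_tibble(maps)[, c("cell_id", "month", "q", "q_obs")],
               by = c("cell_id", "month", "q")) %>%
    group_by(.data$month) %>%
    summarise(quantile_rmse = sqrt(mean((.data$q_corr - .data$q_obs)^2)),
              .groups = "drop")

  structure(
    list(hist_fine = hist_fine, fut_fine = fut_fine,
         hist_corrected = hist_corr, fut_corrected = fut_corr,
         bias_maps = maps,
         diagnostics = list(pre_mean_bias = mean_bias(model_hist),
                            post_mean_bias = mean_bias(hist_corr),
                            month_rmse = month_rmse)),
    class = "oz_downscale"
  )
}

#' @export
print.oz_downscale <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0("<oz_downscale> mean bias vs obs: %+.2f ppb before, ",
                     "%+.2f ppb after correction\n"),
              d$pre_mean_bias, d$post_mean_bias))
  invisible(x)
}
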