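#' Kinetic parameters of the fed-batch penicillin simulator
#'
#' A simplified Bajpai-Reuss-type fed-batch model: Contois-limited
#' biomass growth, substrate-inhibited penicillin production with a
#' density-dependent oxygen-transfer limitation, first-order product
#' hydrolysis and biomass decay, and dilution by a stepwise substrate
#' feed. The default recipe runs a 400 h batch sampled every 0.5 h with
#' three operating phases driven by the feed schedule: batch growth (no
#' feed, 0-45 h), fed-batch production (27 g/h, 45-240 h) and a
#' starvation/autolysis phase (feed off, 240-400 h). A temperature-shift
#' recipe (298/297/296 K) accompanies the phases. Under the defaults the
#' penicillin concentration climbs to roughly 1 g/L, peaks mid-run as
#' rising cell density throttles production, and decays by hydrolysis
#' afterwards; the constants do not replicate any external simulator
#' numerically.
#'
#' @param mu_x maximum specific growth rate (1/h).
#' @param K_x Contois saturation constant (g substrate / g biomass).
#' @param mu_p specific production rate constant (1/h).
#' @param K_p production saturation constant (g/L).
#' @param K_I substrate inhibition constant (g/L).
#' @param X_crit biomass density (g/L) above which oxygen transfer limits
#'   production; \code{ox_pow} sets the sharpness of the limitation.
#' @param ox_pow Hill exponent of the oxygen-limitation factor.
#' @param Y_xs,Y_ps biomass/product yields on substrate (g/g).
#' @param m_x maintenance coefficient (1/h).
#' @param k_d biomass decay (autolysis) rate (1/h).
#' @param k_h penicillin hydrolysis rate (1/h).
#' @param s_f substrate concentration of the feed (g/L).
#' @param k_evap evaporative volume loss rate (1/h).
#' @param feed_times,feed_rates stepwise feed schedule: from
#'   \code{feed_times[i]} (h) the substrate mass feed is
#'   \code{feed_rates[i]} (g/h).
#' @param X0,S0,P0,V0 initial biomass, substrate, penicillin (g/L) and
#'   culture volume (L).
#' @param duration batch duration (h).
#' @param dt sampling interval (h).
#' @param temp_setpoints fermenter temperature per feed phase (K).
#' @param agit_setpoints agitator power recipe per feed phase (W).
#' @param air_setpoints aeration rate recipe per feed phase (L/h).
#' @param feed_temp substrate feed temperature setpoint (K).
#' @param ph_setpoint controlled pH.
#' @param noise_frac measurement noise sd as a fraction of each measured
#'   channel's range (default 0.01).
#' @return a validated parameter list of class \code{kinetic_params}.
#' @export
kinetic_params <- function(mu_x = 0.092, K_x = 0.15, mu_p = 0.010,
                           K_p = 2e-4, K_I = 0.10, X_crit = 8.0,
                           ox_pow = 12, Y_xs = 0.45, Y_ps = 0.90,
                           m_x = 0.014, k_d = 0.004, k_h = 0.018,
                           s_f = 300, k_evap = 5e-4,
                           feed_times = c(0, 45, 240),
                           feed_rates = c(0, 27, 0),
                           X0 = 0.1, S0 = 15, P0 = 0, V0 = 100,
                           duration = 400, dt = 0.5,
                           temp_setpoints = c(298, 297, 296),
                           agit_setpoints = c(29, 32, 30),
                           air_setpoints = c(6, 8.5, 7),
                           feed_temp = 296, ph_setpoint = 5.0,
                           noise_frac = 0.01) {
  p <- list(mu_x = mu_x, K_x = K_x, mu_p = mu_p, K_p = K_p, K_I = K_I,
            X_crit = X_crit, ox_pow = ox_pow,
            Y_xs = Y_xs, Y_ps = Y_ps, m_x = m_x, k_d = k_d, k_h = k_h,
            s_f = s_f, k_evap = k_evap,
            feed_times = feed_times, feed_rates = feed_rates,
            X0 = X0, S0 = S0, P0 = P0, V0 = V0,
            duration = duration, dt = dt,
            temp_setpoints = temp_setpoints,
            agit_setpoints = agit_setpoints, air_setpoints = air_setpoints,
            feed_temp = feed_temp,
            ph_setpoint = ph_setpoint, noise_frac = noise_frac)
  rates <- c(mu_x, mu_p, m_x, k_d, k_h, Y_xs, Y_ps, K_x, K_p, K_I,
             X_crit, ox_pow, s_f, k_evap, feed_rates, X0, S0, P0, V0,
             noise_frac)
  if (any(rates < 0)) stop("rates, yields and concentrations must be >= 0")
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  if (length(feed_times) != length(feed_rates))
    stop("feed_times and feed_rates must have equal length")
  if (is.unsorted(feed_times, strictly = TRUE))
    stop("feed_times must be strictly increasing")
  if (length(temp_setpoints) != length(feed_times) ||
      length(agit_setpoints) != length(feed_times) ||
      length(air_setpoints) != length(feed_times))
    stop("one temperature/agitation/aeration setpoint per feed phase required")
  structure(p, class = "kinetic_params")
}

# feed mass rate (g/h) at time t under the stepwise schedule
feed_rate_at <- function(params, t) {
  idx <- findInterval(t, params$feed_times)
  ifelse(idx < 1L, 0, params$feed_rates[pmax(idx, 1L)])
}

ferment_deriv <- function(t, state, params) {
  X <- max(state[1L], 0); S <- max(state[2L], 0)
  P <- max(state[3L], 0); V <- max(state[4L], 1e-6)
  Fm <- feed_rate_at(params, t)          # substrate mass feed, g/h
  Fv <- Fm / params$s_f                  # volumetric feed, L/h
  mu <- params$mu_x * S / (params$K_x * X + S + 1e-12)
  ox <- 1 / (1 + (X / params$X_crit)^params$ox_pow)
  mupp <- params$mu_p * ox * S / (params$K_p + S + S^2 / params$K_I)
  # maintenance saturates in S so every consumption term vanishes at S = 0
  maint <- params$m_x * X * S / (1e-3 + S)
  dX <- mu * X - params$k_d * X - X * Fv / V
  dS <- -mu * X / params$Y_xs - mupp * X / params$Y_ps - maint +
    Fv * (params$s_f - S) / V
  dP <- mupp * X - params$k_h * P - P * Fv / V
  dV <- Fv - params$k_evap * V
  list(c(dX, dS, dP, dV))
}

#' Simulate one fed-batch fermentation
#'
#' Integrates the four-state kinetic model (biomass, substrate,
#' penicillin, volume) piecewise across the feed-schedule breakpoints
#' with \code{deSolve::lsoda}, then derives the seven measured channels:
#' u1 = culture volume, u2 = agitator power and u7 = aeration rate
#' (recipe setpoints per operating phase), u3 = pH and u4/u5 =
#' feed/fermenter temperatures (controlled setpoints with a small
#' autocorrelated wander), u6 = substrate feed rate. All channels carry
#' additive Gaussian noise with sd = \code{noise_frac} x channel range.
#' The noiseless state trajectory depends only on the parameters; the
#' seed drives measurement noise alone.
#'
#' @param params a [kinetic_params()] list.
#' @param seed integer seed for measurement noise.
#' @return an object of class \code{batch_trajectory}: \code{time},
#'   \code{states} (noise-free data frame X, S, P, V), \code{U}
#'   (measured u1..u7 matrix), \code{y} (penicillin concentration, g/L)
#'   and \code{noise_sd} per channel.
#' @export
simulate_batch <- function(params, seed = 1L) {
  times <- seq(0, params$duration, by = params$dt)
  breaks <- unique(c(0, params$feed_times[params$feed_times > 0 &
                                            params$feed_times < params$duration],
                     params$duration))
  state <- c(X = params$X0, S = params$S0, P = params$P0, V = params$V0)
  out <- NULL
  for (b in seq_len(length(breaks) - 1L)) {
    seg_t <- unique(c(breaks[b], times[times > breaks[b] & times < breaks[b + 1L]],
                      breaks[b + 1L]))
    seg <- deSolve::lsoda(state, seg_t, ferment_deriv, params,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 20000L)
    if (attr(seg, "istate")[1L] < 0)
      stop("integration failure; check the kinetic parameters")
    seg <- as.data.frame(seg)
    state <- unlist(seg[nrow(seg), c("X", "S", "P", "V")])
    out <- rbind(out, if (is.null(out)) seg else seg[-1L, ])
  }
  out <- out[match(times, out$time), ]
  states <- data.frame(X = pmax(out$X, 0), S = pmax(out$S, 0),
                       P = pmax(out$P, 0), V = out$V)

  phase <- pmax(findInterval(times, params$feed_times), 1L)
  clean <- cbind(
    u1 = states$V,
    u2 = params$agit_setpoints[phase],
    u3 = rep(params$ph_setpoint, length(times)),
    u4 = rep(params$feed_temp, length(times)),
    u5 = params$temp_setpoints[phase],
    u6 = feed_rate_at(params, times),
    u7 = params$air_setpoints[phase]
  )
  ranges <- apply(clean, 2L, function(v) diff(range(v)))
  noise_sd <- params$noise_frac * ifelse(ranges > 0, ranges, 1)

  U <- with_seed(seed, {
    nt <- length(times)
    wander <- function(sd_w) {
      w <- numeric(nt)
      e <- stats::rnorm(nt, 0, sd_w * sqrt(1 - 0.95^2))
      for (i in seq_len(nt)) w[i] <- if (i == 1L) e[1L] else 0.95 * w[i - 1L] + e[i]
      w
    }
    out_u <- clean
    # controlled channels wander slowly around their setpoints, with an
    # amplitude matching the measurement noise so control stays tight
    out_u[, "u3"] <- out_u[, "u3"] + wander(noise_sd[3L])
    out_u[, "u4"] <- out_u[, "u4"] + wander(noise_sd[4L])
    out_u[, "u5"] <- out_u[, "u5"] + wander(noise_sd[5L])
    out_u + matrix(stats::rnorm(length(clean), 0, rep(noise_sd, each = nt)),
                   nrow = nt)
  })

  structure(list(time = times, states = states, U = U, y = states$P,
                 noise_sd = noise_sd, params = params),
            class = "batch_trajectory")
}

#' @export
print.batch_trajectory <- function(x, ...) {
  cat(sprintf(
    "batch_trajectory: %d samples over %g h; penicillin %.3f -> %.3f g/L (max %.3f)\n",
    length(x$time), max(x$time), x$y[1L], x$y[length(x$y)], max(x$y)))
  invisible(x)
}

#' Generate a process dataset from the simulator
#'
#' Draws \code{n_samples} rows of the seven measured channels plus the
#' quality variable from one batch (or consecutive seeded batches when
#' one is too short). The default configuration yields 800 rows, meant
#' to be split 400/400 into training and test downstream.
#'
#' @param params a [kinetic_params()] list.
#' @param n_samples number of rows.
#' @param seed integer seed (batch b uses seed + b - 1).
#' @return a [process_dataset()] with inputs u1..u7 and quality y.
#' @export
generate_dataset <- function(params = kinetic_params(), n_samples = 800L,
                             seed = 1L) {
  per_batch <- length(seq(0, params$duration, by = params$dt))
  n_batches <- ceiling(n_samples / per_batch)
  U <- NULL; y <- NULL
  for (b in seq_len(n_batches)) {
    traj <- simulate_batch(params, seed = seed + b - 1L)
    U <- rbind(U, traj$U)
    y <- c(y, traj$y)
  }
  if (nrow(U) < n_samples) stop("unachievable n_samples")
  process_dataset(U[seq_len(n_samples), , drop = FALSE],
                  y = y[seq_len(n_samples)])
}

#' A labeling oracle over a ground-truth dataset
#'
#' Stands in for the laboratory analyst of the active-learning loop:
#' returns the stored quality value of requested samples and counts
#' queries for the annotation-cost report.
#'
#' @param data a [process_dataset()] with ground-truth y for all rows.
#' @return an object of class \code{label_oracle} with functions
#'   \code{query(ids)} and \code{count()}.
#' @export
make_oracle <- function(data) {
  if (is.null(data$y) || anyNA(data$y))
    stop("oracle needs ground-truth y for every sample")
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  query <- function(ids) {
    if (anyDuplicated(ids)) stop("repeated id in one oracle call")
    idx <- match(ids, data$ids)
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(ids[is.na(idx)], collapse = ", "))
    env$count <- env$count + length(ids)
    data$y[idx]
  }
  structure(list(query = query, count = function() env$count),
            class = "label_oracle")
}
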