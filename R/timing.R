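#' Per-client timing distribution parameters
#'
#' The simulated wall time of client k in one round is
#' `T_k = T_down + T_up + T_val * N_val + T_train * N_train`, where each
#' component time is drawn from a client-specific normal law N(mu_x, sigma_x)
#' (x in down, up, val, train; val/train are per-sample times, down/up
#' per-round constants). Negative draws are floored at `1e-3 * mu` (normal laws
#' are unbounded below; the floor keeps times positive and is recorded here).
#'
#' @param mu_down,mu_up Per-round communication times, simulated seconds.
#' @param mu_val,mu_train Per-sample validation / training times, seconds.
#' @param sigma_down,sigma_up,sigma_val,sigma_train Standard deviations
#'   (nonnegative).
#' @return An object of class `client_timing_params`.
#' @export
client_timing_params <- function(mu_down = 300, mu_up = 300,
                                 mu_val = 6, mu_train = 60,
                                 sigma_down = 0, sigma_up = 0,
                                 sigma_val = 0, sigma_train = 0) {
  mus <- c(down = unname(mu_down), up = unname(mu_up), val = unname(mu_val),
           train = unname(mu_train))
  sds <- c(down = unname(sigma_down), up = unname(sigma_up),
           val = unname(sigma_val), train = unname(sigma_train))
  if (any(mus <= 0)) stop("timing means must be positive")
  if (any(sds < 0)) stop("timing standard deviations must be nonnegative")
  structure(list(mu = mus, sigma = sds), class = "client_timing_params")
}

#' Sample one round's simulated time for a client
#'
#' Draws the four time components from their normal laws (one draw per
#' component per round; per-sample components are then scaled by the split
#' sizes) and returns the component times and their sum `T_k`. Consumes the
#' current RNG stream; callers that need a fairness-protected stream should
#' wrap the call in a dedicated seed (the orchestrator does).
#'
#' @param params A [client_timing_params()].
#' @param n_train,n_val Nonnegative sample counts of the client's splits.
#' @return List with `t_down`, `t_up`, `t_val`, `t_train` (totals, not
#'   per-sample) and `t_k`.
#' @export
sample_client_time <- function(params, n_train, n_val) {
  stopifnot(inherits(params, "client_timing_params"), n_train >= 0, n_val >= 0)
  draw <- function(x) {
    v <- stats::rnorm(1, params$mu[[x]], params$sigma[[x]])
    max(v, 1e-3 * params$mu[[x]])
  }
  t_down <- draw("down")
  t_up <- draw("up")
  t_val <- draw("val") * n_val
  t_train <- draw("train") * n_train
  list(t_down = t_down, t_up = t_up, t_val = t_val, t_train = t_train,
       t_k = t_down + t_up + t_val + t_train)
}

#' Round time: the slowest selected collaborator
#'
#' A federated round finishes when its slowest participant finishes, so the
#' round time is the maximum of the selected clients' `T_k`.
#'
#' @param client_times Numeric vector (or list of [sample_client_time()]
#'   results) for the selected clients.
#' @return The maximum `T_k`.
#' @export
round_time <- function(client_times) {
  if (is.list(client_times)) {
    client_times <- vapply(client_times, function(x) x$t_k, numeric(1))
  }
  if (length(client_times) == 0) stop("round_time of an empty selection")
  max(client_times)
}

#' Build a per-client timing profile for a federation
#'
#' Timing parameters are fixed per client for the whole experiment and shared
#' across all compared algorithms. The "size_proportional" profile makes the
#' per-sample training time dominate, so clients with many samples are the
#' slowest — the regime in which client selection matters. "uniform" gives all
#' clients identical parameters. "custom" uses the parameters supplied in
#' `base` verbatim for every client (or a list of per-client parameters).
#'
#' @param fed A `federation`.
#' @param profile "size_proportional" (default), "uniform" or "custom".
#' @param seed Seed for the per-client jitter of "size_proportional".
#' @param base A [client_timing_params()] giving the center of the profile, or
#'   for "custom" either one such object or a named list (one per site).
#' @param rel_sigma Relative sd assigned to every component (default 0.05);
#'   set 0 for deterministic timing.
#' @param jitter Relative spread of per-client mean perturbations for
#'   "size_proportional" (default 0.2).
#' @return Named list of [client_timing_params()], one per client.
#' @export
make_timing_profile <- function(fed,
                                profile = c("size_proportional", "uniform",
                                            "custom"),
                                seed = 1L,
                                base = client_timing_params(),
                                rel_sigma = 0.05, jitter = 0.2) {
  profile <- match.arg(profile)
  stopifnot(inherits(fed, "federation"))
  ids <- vapply(fed$clients, function(cl) cl$site_id, character(1))

  if (profile == "custom") {
    if (inherits(base, "client_timing_params")) {
      out <- rep(list(base), length(ids))
      names(out) <- ids
      return(out)
    }
    stopifnot(all(ids %in% names(base)))
    return(base[ids])
  }

  params_for <- function(mult) {
    client_timing_params(
      mu_down = base$mu[["down"]] * mult["down"],
      mu_up = base$mu[["up"]] * mult["up"],
      mu_val = base$mu[["val"]] * mult["val"],
      mu_train = base$mu[["train"]] * mult["train"],
      sigma_down = base$mu[["down"]] * mult["down"] * rel_sigma,
      sigma_up = base$mu[["up"]] * mult["up"] * rel_sigma,
      sigma_val = base$mu[["val"]] * mult["val"] * rel_sigma,
      sigma_train = base$mu[["train"]] * mult["train"] * rel_sigma
    )
  }

  out <- with_stream(derive_seed(seed, "timing_profile"), {
    lapply(ids, function(id) {
      mult <- if (profile == "uniform") {
        c(down = 1, up = 1, val = 1, train = 1)
      } else {
        # per-client hardware heterogeneity; per-sample train time dominates
        m <- stats::runif(4, 1 - jitter, 1 + jitter)
        c(down = m[1], up = m[2], val = m[3], train = m[4])
      }
      params_for(mult)
    })
  })
  names(out) <- ids
  out
}

#' Serialize a timing profile to JSON
#'
#' @param profile A named list of [client_timing_params()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timing_profile <- function(profile, path) {
  obj <- lapply(profile, function(p) list(mu = as.list(p$mu),
                                          sigma = as.list(p$sigma)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
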