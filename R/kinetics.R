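#' Three-pool kinetic model of focal adhesion protein binding
#'
#' FA proteins are modelled as one mobile pool plus two bound pools that
#' differ only in residence time: a *dynamically* bound pool (medium
#' residence times, tens of seconds) and a *stably* bound pool (long
#' residence times, many minutes). The reaction scheme is
#'
#' \deqn{M_{mob} \rightleftharpoons M_{med}, \quad
#'       M_{med} \rightarrow M_{long} \rightarrow M_{mob}}
#'
#' i.e. all stable binding is routed through the dynamic state: a mobile
#' molecule first binds dynamically, may then convert to the stable state,
#' and stably bound molecules release directly back to the mobile pool.
#'
#' A parameter set is a data frame (one row per condition) with columns
#' `f_medium`, `f_long` (steady-state bound fractions of the whole pool,
#' each in \[0, 1) with `f_medium + f_long < 1`) and `t_r_medium_s`,
#' `t_r_long_s` (mean residence times in seconds). [kinetic_params()]
#' builds and validates such a tibble; [derive_rates()] converts fractions
#' and residence times to the effective pseudo-first-order rate constants;
#' [steady_state_fractions()] inverts that conversion.
#'
#' @param f_medium,f_long Steady-state fractions of the pool in the
#'   dynamically / stably bound state.
#' @param t_r_medium_s,t_r_long_s Mean residence times (seconds) of the two
#'   bound states.
#' @return A tibble of class `kinetic_params` with the four columns above.
#' @examples
#' p <- kinetic_params(0.30, 0.45, 50, 1800)
#' derive_rates(p)
#' @export
kinetic_params <- function(f_medium, f_long, t_r_medium_s, t_r_long_s) {
  p <- tibble::tibble(
    f_medium = as.numeric(f_medium),
    f_long = as.numeric(f_long),
    t_r_medium_s = as.numeric(t_r_medium_s),
    t_r_long_s = as.numeric(t_r_long_s)
  )
  validate_kinetic_params(p)
  class(p) <- c("kinetic_params", class(p))
  p
}

validate_kinetic_params <- function(p) {
  req <- c("f_medium", "f_long", "t_r_medium_s", "t_r_long_s")
  missing <- setdiff(req, names(p))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "kinetic parameters need column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (any(p$f_medium < 0 | p$f_long < 0)) {
    rlang::abort("bound fractions must be nonnegative")
  }
  if (any(p$f_medium + p$f_long >= 1)) {
    rlang::abort("f_medium + f_long must be < 1 (the remainder is the mobile pool)")
  }
  if (any(p$t_r_medium_s <= 0 | p$t_r_long_s <= 0)) {
    rlang::abort("residence times must be > 0")
  }
  if (any(p$f_long > 0 & p$f_medium == 0)) {
    rlang::abort(paste0(
      "degenerate model: f_long > 0 requires f_medium > 0 ",
      "(stable binding is routed through the dynamic state)"
    ))
  }
  invisible(p)
}

#' Off-rate constant from a mean residence time
#'
#' The off-rate constant of a bound state is the reciprocal of its mean
#' residence time, `k_off = 1 / t_r`.
#'
#' @param t_r Mean residence time(s) in seconds; must be positive.
#' @return Off-rate constant(s) in 1/s.
#' @examples
#' k_off_from_residence(600) # 1/600 s^-1
#' @export
k_off_from_residence <- function(t_r) {
  t_r <- as.numeric(t_r)
  if (any(!is.finite(t_r)) || any(t_r <= 0)) {
    rlang::abort("t_r must be finite and > 0")
  }
  1 / t_r
}

#' Effective rate constants from fractions and residence times
#'
#' Converts bound-fraction sizes and residence times to the four effective
#' pseudo-first-order rate constants of the scheme. Off rates are
#' `k_off = 1/t_r` for each bound state; the on rates follow from the
#' steady-state balances
#' \deqn{k_{on,med} = \frac{F_{med}}{1 - F_{med} - F_{long}}
#'       (k_{off,med} + k_{on,long})}
#' \deqn{k_{on,long} = \frac{F_{long}}{F_{med}} k_{off,long}}
#' where `k_on_long` is the conversion rate of a dynamically bound molecule
#' to the stable state.
#'
#' @param params A data frame with columns `f_medium`, `f_long`,
#'   `t_r_medium_s`, `t_r_long_s` (see [kinetic_params()]).
#' @return The input tibble with rate columns `k_off_medium`, `k_off_long`,
#'   `k_on_medium`, `k_on_long` (all 1/s) appended.
#' @examples
#' derive_rates(kinetic_params(0.30, 0.45, 50, 1800))
#' @export
derive_rates <- function(params) {
  validate_kinetic_params(params)
  p <- tibble::as_tibble(params)
  k_off_medium <- k_off_from_residence(p$t_r_medium_s)
  k_off_long <- k_off_from_residence(p$t_r_long_s)
  k_on_long <- ifelse(p$f_long == 0, 0, p$f_long / p$f_medium * k_off_long)
  k_on_medium <- ifelse(
    p$f_medium == 0,
    0,
    p$f_medium / (1 - p$f_medium - p$f_long) * (k_off_medium + k_on_long)
  )
  out <- dplyr::mutate(
    p,
    k_off_medium = k_off_medium,
    k_off_long = k_off_long,
    k_on_medium = k_on_medium,
    k_on_long = k_on_long
  )
  stopifnot(all(is.finite(c(out$k_on_medium, out$k_on_long))),
            all(c(out$k_on_medium, out$k_on_long) >= 0))
  out
}

#' Steady-state pool fractions from a rate set
#'
#' Solves the linear steady-state balance of the scheme
#' `mobile <-> medium, medium -> long -> mobile` for the stationary
#' occupancies. This is the exact inverse of [derive_rates()] and the
#' closed-form oracle that the Monte Carlo simulator is checked against.
#'
#' @param rates A data frame with columns `k_on_medium`, `k_off_medium`,
#'   `k_on_long`, `k_off_long` (1/s), e.g. the output of [derive_rates()].
#' @return A tibble with columns `f_mobile`, `f_medium`, `f_long` summing
#'   to 1 in each row.
#' @examples
#' steady_state_fractions(derive_rates(kinetic_params(0.3, 0.45, 50, 1800)))
#' @export
steady_state_fractions <- function(rates) {
  r <- tibble::as_tibble(rates)
  req <- c("k_on_medium", "k_off_medium", "k_on_long", "k_off_long")
  if (!all(req %in% names(r))) {
    rlang::abort(paste0("rates need columns: ", paste(req, collapse = ", ")))
  }
  if (any(r[req] < 0)) rlang::abort("rates must be nonnegative")
  one <- function(kon_m, koff_m, kon_l, koff_l) {
    if (kon_m == 0) return(c(1, 0, 0))
    exit_med <- koff_m + kon_l
    if (exit_med == 0) return(c(0, 1, 0))        # medium state absorbing
    if (kon_l > 0 && koff_l == 0) return(c(0, 0, 1)) # long state absorbing
    med <- kon_m / exit_med                       # relative to mobile = 1
    lng <- if (kon_l == 0) 0 else med * kon_l / koff_l
    tot <- 1 + med + lng
    c(1, med, lng) / tot
  }
  m <- mapply(one, r$k_on_medium, r$k_off_medium, r$k_on_long, r$k_off_long)
  tibble::tibble(f_mobile = m[1, ], f_medium = m[2, ], f_long = m[3, ])
}

#' Read/write kinetic parameters as JSON
#'
#' Serialization uses the keys `f_medium`, `f_long`, `t_r_medium_s`,
#' `t_r_long_s`.
#'
#' @param params A `kinetic_params` tibble.
#' @param path File path.
#' @return `write_kinetic_params()` returns `path` invisibly;
#'   `read_kinetic_params()` returns a `kinetic_params` tibble.
#' @export
write_kinetic_params <- function(params, path) {
  validate_kinetic_params(params)
  cols <- c("f_medium", "f_long", "t_r_medium_s", "t_r_long_s")
  jsonlite::write_json(as.list(params[cols]), path, digits = NA)
  invisible(path)
}

#' @rdname write_kinetic_params
#' @export
read_kinetic_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kinetic_params(x$f_medium, x$f_long, x$t_r_medium_s, x$t_r_long_s)
}
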