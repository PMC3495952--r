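#' Load a run configuration from YAML or JSON
#'
#' Parses and validates a configuration with blocks `model` (fields of
#' [walker_params()]; omitted fields take the defaults), `numerics`
#' (fields of [walker_numerics()]), `pulse` (fields of [pulse_train()]; the
#' whole block optional), `experiment` and `output` (free-form lists passed
#' through). Unknown keys anywhere are rejected with a field-level message.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return a list of class `run_config` with elements `model`
#'   (a `walker_params`), `numerics` (a `walker_numerics`), `pulse`
#'   (a `pulse_train` or `NULL`), `experiment`, `output`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  check_keys <- function(block, allowed, where) {
    extra <- setdiff(names(block), allowed)
    if (length(extra)) {
      stop("load_config: unknown key(s) in ", where, ": ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  check_keys(raw, c("model", "numerics", "pulse", "experiment", "output"), "config")
  model <- raw$model %||% list()
  check_keys(model, c("m", "L", "l", "g", "alpha", "mu", "k"), "model")
  numerics <- raw$numerics %||% list()
  check_keys(numerics, c("rtol", "atol", "h_max", "h_init", "fixed_step", "strict"),
             "numerics")
  pulse <- NULL
  if (!is.null(raw$pulse)) {
    check_keys(raw$pulse, c("amplitude", "width", "period", "offset", "leg",
                            "gating", "eps_cap"), "pulse")
    pulse <- do.call(pulse_train, raw$pulse)
  }
  structure(list(
    model = do.call(walker_params, model),
    numerics = do.call(walker_numerics, numerics),
    pulse = pulse,
    experiment = raw$experiment %||% list(),
    output = raw$output %||% list()
  ), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result table or summary to disk
#'
#' Time/stride series (data frames) are written as CSV with a comment
#' header carrying the package version and a configuration hash; floating
#' point is serialized at 12 significant digits, enough for a bit-stable
#' round trip at that precision. Summary lists are written as JSON.
#'
#' @param result a data frame (CSV) or list (JSON).
#' @param path output file path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @param config optional `run_config` (hashed into the header).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = NULL, config = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  ver <- as.character(utils::packageVersion("anklewalker"))
  hash <- if (is.null(config)) "none" else
    format(sum(utf8ToInt(paste(deparse(unclass(config)), collapse = ""))), scientific = FALSE)
  if (format == "json") {
    jsonlite::write_json(c(list(.package = paste0("anklewalker ", ver),
                                .config_hash = hash), result),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    df <- as.data.frame(result)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# anklewalker %s config_hash=%s", ver, hash), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_results_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Canonical constants from independent brute-force oracles
#'
#' Recomputes the constants that anchor the whole analysis from first
#' principles, deliberately avoiding the closed-form expressions the rest
#' of the package uses, so they can serve as an independent cross-check:
#'
#' * `a` — toe offset from the flat-foot construction;
#' * `psi0` — ankle angle at double-stance onset, via explicit
#'   circle-circle intersection for the ankle point;
#' * `theta_f` — end of double stance, by bisection on `psi(theta) - mu`
#'   with `psi` from the circle oracle;
#' * `W` — spring work per step, by numerical quadrature of the torque
#'   over the ankle excursion;
#' * `c` — step-map constant `2*W/(m*L^2)`;
#' * `v_C`, `theta_dot_star` — fixed point from the work-energy balance
#'   `(1 - cos^2 2*alpha) * KE_pre = W` (no closed-form shortcut);
#' * `k_C` — critical stiffness by bisection on the quadrature-based
#'   apex-energy margin;
#' * `A_pulse` — standard pulse amplitude, 10% of the quadrature peak
#'   torque.
#'
#' @param params a [walker_params()] object.
#' @return named list of constants.
#' @export
make_fixtures <- function(params = walker_params()) {
  params <- as_walker_params(params)
  m <- params$m; L <- params$L; l <- params$l; g <- params$g
  alpha <- params$alpha; mu <- params$mu; k <- params$k
  a <- 2 * L * sin(alpha) - l

  # ankle point by circle-circle intersection: |DA| = l about A, |DC| = L about C
  psi_oracle <- function(theta) {
    A <- c(-a, 0)
    C <- c(-L * sin(theta), L * cos(theta))
    d <- sqrt(sum((C - A)^2))
    x <- (l^2 - L^2 + d^2) / (2 * d) # along A->C
    h2 <- l^2 - x^2
    if (h2 < 0) stop("no linkage solution")
    h <- sqrt(h2)
    u <- (C - A) / d
    n <- c(-u[2], u[1])
    D1 <- A + x * u + h * n
    D2 <- A + x * u - h * n
    # branch continuous with the flat foot: cross((D - A), (C - A)) < 0
    crossz <- function(D) (D[1] - A[1]) * (C[2] - A[2]) - (D[2] - A[2]) * (C[1] - A[1])
    D <- if (crossz(D1) < 0) D1 else D2
    v1 <- A - D; v2 <- C - D
    acos(sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))
  }

  psi0 <- psi_oracle(alpha)

  bisect <- function(f, lo, hi, tol = 1e-14, it = 200) {
    flo <- f(lo)
    for (i in seq_len(it)) {
      mid <- 0.5 * (lo + hi)
      fm <- f(mid)
      if (abs(hi - lo) < tol) break
      if ((fm > 0) == (flo > 0)) { lo <- mid; flo <- fm } else hi <- mid
    }
    0.5 * (lo + hi)
  }
  # keep the bracket clear of the linkage singularity AC = l + L
  s_sing <- (a^2 + L^2 - (l + L)^2) / (2 * a * L)
  th_lo <- if (abs(s_sing) <= 1) asin(s_sing) + 1e-9 else -alpha
  theta_f <- bisect(function(th) psi_oracle(th) - mu, alpha, th_lo)

  W <- stats::integrate(function(psi) k * pmax(mu - psi, 0), psi0, mu,
                        rel.tol = 1e-12)$value
  cc <- 2 * W / (m * L^2)

  # fixed point from the collision energy balance, solved numerically
  c2a <- cos(2 * alpha)
  ke_balance <- function(v) (1 - c2a^2) * 0.5 * m * v^2 - W
  v_C <- bisect(ke_balance, 1e-6, 1e3)
  theta_dot_star <- -c2a * v_C / L

  # critical stiffness: apex KE of the fixed-point gait hits zero
  apex_margin <- function(kk) {
    Wk <- stats::integrate(function(psi) kk * pmax(mu - psi, 0), psi0, mu,
                           rel.tol = 1e-12)$value
    vCk <- bisect(function(v) (1 - c2a^2) * 0.5 * m * v^2 - Wk, 1e-9, 1e3)
    0.5 * m * (c2a * vCk)^2 + Wk - m * g * L * (1 - cos(alpha))
  }
  k_C <- bisect(apex_margin, 1e-3, 1e4)

  list(a = a, psi0 = psi0, theta_f = theta_f, W = W, c = cc,
       v_C = v_C, theta_dot_star = theta_dot_star, k_C = k_C,
       A_pulse = 0.1 * k * (mu - psi0))
}
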