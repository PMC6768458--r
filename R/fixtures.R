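# Packaged fixture models.  Rule texts are the canonical DSL; reference
# parameter sets are the published figure-caption values for each analysis.

fixture_rules <- list(
  honeybee = paste(
    "U -> A : g_A",
    "U -> B : g_B",
    "A -> U : a_A",
    "B -> U : a_B",
    "A + U -> A + A : r_A",
    "B + U -> B + B : r_B",
    "A + B -> A + U : s",
    "A + B -> B + U : s",
    sep = "\n"),
  brusselator = paste(
    "(alpha) -> X : chi",
    "(beta) + X -> Y : delta",
    "2 X + Y -> 3 X : gamma",
    "X -> EMPTY : xi",
    sep = "\n"),
  lotka_volterra = paste(
    "(A) + X -> 2 X : alpha",
    "X + Y -> 2 Y : beta",
    "Y -> EMPTY : gamma",
    sep = "\n"),
  toy_birth_annihilation = "(A) -> X : k\nX + X -> EMPTY : h",
  birth_death = "EMPTY -> X : b\nX -> EMPTY : d"
)

#' Rate parameters of the stop-signal model from site qualities
#'
#' The honeybee nest-site model is usually analysed in terms of the mean
#' quality mu and quality difference Delta of the two sites: discovery and
#' recruitment rates equal the site quality `v = mu +/- Delta/2`, abandonment
#' its reciprocal, and cross-inhibition acts at rate s.
#'
#' @param mu mean site quality.
#' @param Delta quality difference (site A minus site B).
#' @param s stop-signalling rate.
#' @return named list binding the eight rule rates of the `honeybee` fixture.
#' @export
honeybee_rate_params <- function(mu, Delta, s) {
  v_A <- mu + Delta / 2
  v_B <- mu - Delta / 2
  list(g_A = v_A, g_B = v_B, a_A = 1 / v_A, a_B = 1 / v_B,
       r_A = v_A, r_B = v_B, s = s)
}

#' Load a packaged fixture model
#'
#' Available fixtures: `"honeybee"` (the 8-rule stop-signal model of
#' collective nest-site choice), `"honeybee_reduced"` (the same model after
#' eliminating the uncommitted class, `U = N - A - B`, and re-expressing the
#' rates through mean quality mu and quality difference Delta),
#' `"brusselator"`, `"lotka_volterra"`, `"toy_birth_annihilation"`
#' (`(A) -> X`, `X + X -> EMPTY`), and `"birth_death"`.
#'
#' @param name fixture name.
#' @return a list with elements `model` (a `reaction_model`), `params`
#'   (named list of reference parameter sets, keyed by the figure they
#'   reproduce), and `init` (reference initial conditions where published).
#' @examples
#' fx <- load_fixture("honeybee_reduced")
#' fx$params$fig4_lower_right
#' @export
load_fixture <- function(name) {
  known <- c(names(fixture_rules), "honeybee_reduced")
  if (!name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(sort(known), collapse = ", "), call. = FALSE)
  }
  if (name == "honeybee_reduced") {
    model <- substitute_model(
      substitute_model(
        substitute_model(parse_model(fixture_rules$honeybee), "U = N - A - B"),
        "a_A = 1/v_A, a_B = 1/v_B, g_A = v_A, g_B = v_B, r_A = v_A, r_B = v_B"),
      "v_A = mu + Delta/2, v_B = mu - Delta/2")
    params <- list(
      fig4_lower_right = list(Delta = 0.0, mu = 3.0, s = 10.0, N = 20),
      fig5_left = list(Delta = 0.0, mu = 4.0, N = 1),
      fig5_centre = list(Delta = 0.1, mu = 4.0, N = 1),
      fig5_right = list(mu = 4.0, s = 4.0, N = 1)
    )
    init <- list()
  } else {
    model <- parse_model(fixture_rules[[name]])
    params <- switch(name,
      honeybee = list(
        fig6_left = c(honeybee_rate_params(mu = 3.0, Delta = 0.0, s = 3.0),
                      list(V = 50, t_max = 10, runs = 10))
      ),
      brusselator = list(
        fig3_left = list(chi = 2.0, delta = 2.0, gamma = 2.0, xi = 2.0,
                         Phi_alpha = 2.0, Phi_beta = 2.0, V = 10),
        fig3_right = list(chi = 2.0, delta = 2.0, gamma = 2.0, xi = 2.0,
                          Phi_alpha = 2.0, Phi_beta = 5.5, V = 10)
      ),
      lotka_volterra = list(
        fig4_upper_left = list(alpha = 2.0, beta = 2.0, gamma = 2.0,
                               Phi_A = 2.0)
      ),
      toy_birth_annihilation = list(
        default = list(k = 1.0, h = 1.0, Phi_A = 1.0)
      ),
      birth_death = list(
        default = list(b = 2.0, d = 1.0)
      )
    )
    init <- switch(name,
      honeybee = list(fig6_left = c(U = 50, A = 0, B = 0)),
      brusselator = list(fig3 = c(Phi_X = 1.0, Phi_Y = 1.0)),
      list()
    )
  }
  list(model = model, params = params, init = init)
}
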