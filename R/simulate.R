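#' Construct a generating item bank
#'
#' Bundles generating partial-credit item parameters (and optional injected
#' differential item functioning) for the simulation functions. Default
#' thresholds are equally spaced and ordered.
#'
#' @param n_items number of items.
#' @param m maximum score per item (single integer; 5 ordered categories
#'   means \code{m = 4}).
#' @param delta item locations; defaults to an equally spaced grid on
#'   \code{[-0.6, 0.6]}.
#' @param tau centered threshold vector shared by all items (length m,
#'   summing to 0), or a list of per-item vectors; default equally spaced
#'   with step 0.6.
#' @param item_ids item names.
#' @param subscale_map optional item-to-subscale map.
#' @return object of class \code{item_bank}: list with \code{item_ids},
#'   \code{beta} (uncentered thresholds), \code{delta}, \code{tau},
#'   \code{subscale_map}, \code{dif} (list of injections, initially empty).
#' @export
item_bank <- function(n_items = 12, m = 4,
                      delta = seq(-0.6, 0.6, length.out = n_items),
                      tau = seq(-0.45 * (m - 1), 0.45 * (m - 1), length.out = m) / 1.5,
                      item_ids = sprintf("I%02d", seq_len(n_items)),
                      subscale_map = NULL) {
  if (length(delta) != n_items) stop("delta must have one entry per item")
  if (!is.list(tau)) tau <- rep(list(tau), n_items)
  if (length(tau) != n_items) stop("tau list must have one entry per item")
  for (t_i in tau)
    if (abs(sum(t_i)) > 1e-8) stop("centered thresholds must sum to zero")
  beta <- lapply(seq_len(n_items), function(i) delta[i] + tau[[i]])
  names(beta) <- item_ids
  structure(list(item_ids = item_ids, beta = beta,
                 delta = stats::setNames(delta, item_ids),
                 tau = stats::setNames(tau, item_ids),
                 subscale_map = subscale_map, dif = list()),
            class = "item_bank")
}

#' Inject differential item functioning into a generating item bank
#'
#' Modifies the generator so that one item behaves differently for one level
#' of a person covariate. Uniform DIF shifts the item's location (all
#' thresholds) by \code{size} logits for that group; non-uniform DIF gives
#' the group a different discrimination (slope on theta) for that item, so
#' the group difference changes along the trait.
#'
#' @param bank an \code{\link{item_bank}}.
#' @param item item id.
#' @param factor name of the person covariate.
#' @param level the covariate level affected.
#' @param size logit shift (uniform) or slope multiplier offset
#'   (non-uniform: the affected group's slope is \code{1 + size}).
#' @param kind "uniform" or "non-uniform".
#' @return the modified \code{item_bank}; \code{size = 0} leaves the
#'   generator unchanged.
#' @export
inject_dif <- function(bank, item, factor, level, size,
                       kind = c("uniform", "non-uniform")) {
  stopifnot(inherits(bank, "item_bank"))
  kind <- match.arg(kind)
  if (!is.finite(size)) stop("size must be finite")
  if (!item %in% bank$item_ids) stop("unknown item: ", item)
  if (size != 0)
    bank$dif <- c(bank$dif, list(list(item = item, factor = factor,
                                      level = level, size = size, kind = kind)))
  bank
}

# draw one response matrix given person locations and covariates
draw_responses <- function(bank, theta, person_factors = NULL) {
  n <- length(theta)
  I <- length(bank$item_ids)
  scores <- matrix(0L, n, I, dimnames = list(NULL, bank$item_ids))
  for (i in seq_len(I)) {
    beta <- bank$beta[[i]]
    shift <- numeric(n)
    slope <- rep(1, n)
    for (d in bank$dif) {
      if (d$item != bank$item_ids[i]) next
      in_group <- person_factors[[d$factor]] == d$level
      if (d$kind == "uniform") shift[in_group] <- shift[in_group] + d$size
      else slope[in_group] <- slope[in_group] + d$size
    }
    # uniform DIF: item location shifted for the group; non-uniform: the
    # group's kernel uses slope * theta in place of theta
    p <- pcm_probs(slope * theta, beta)
    if (any(shift != 0)) {
      for (v in which(shift != 0))
        p[v, ] <- pcm_probs(slope[v] * theta[v], beta + shift[v])
    }
    u <- stats::runif(n)
    cp <- t(apply(p, 1, cumsum))
    scores[, i] <- rowSums(u > cp[, -ncol(cp), drop = FALSE])
  }
  scores
}

#' Simulate unidimensional partial credit responses
#'
#' Null-model generator: every cell is drawn from the partial credit
#' category distribution at the person's location. Used for calibration of
#' every fit statistic under a correctly specified model.
#'
#' @param n number of persons.
#' @param bank an \code{\link{item_bank}}; defaults to 12 five-category
#'   items with equally spaced locations and thresholds.
#' @param person_mean,person_sd normal person distribution (logits).
#' @param seed random seed (mandatory for reproducibility).
#' @param theta optional explicit person locations (overrides the normal
#'   draw; recycled to length \code{n}).
#' @param person_factors optional data frame of person covariates.
#' @return a \code{\link{response_matrix}}.
#' @export
sim_pcm <- function(n, bank = item_bank(), person_mean = 0, person_sd = 1,
                    seed, theta = NULL, person_factors = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  if (is.null(theta)) theta <- stats::rnorm(n, person_mean, person_sd)
  theta <- rep_len(theta, n)
  scores <- draw_responses(bank, theta, person_factors)
  response_matrix(scores, subscale_map = bank$subscale_map,
                  person_factors = person_factors,
                  item_ids = bank$item_ids,
                  max_score = vapply(bank$beta, length, 1L))
}

#' Default burnout-questionnaire-like item bank
#'
#' 23 five-category items in four subscales (EX 8, MD 5, CI 5, EI 5) with
#' staggered generating locations: exhaustion items sit lowest on the latent
#' continuum (endorsed at milder severity) and emotional-impairment items
#' highest, reproducing the item hierarchy typical of burnout instruments.
#'
#' @param tau centered generating thresholds (equally spaced default).
#' @return an \code{\link{item_bank}} with a subscale map.
#' @export
bat_item_bank <- function(tau = c(-0.9, -0.3, 0.3, 0.9)) {
  sizes <- c(EX = 8, MD = 5, CI = 5, EI = 5)
  centers <- c(EX = -0.45, MD = -0.15, CI = 0.15, EI = 0.45)
  ids <- unlist(lapply(names(sizes), function(s) paste0(s, seq_len(sizes[[s]]))))
  subscales <- rep(names(sizes), sizes)
  delta <- unlist(lapply(names(sizes), function(s)
    centers[[s]] + seq(-0.3, 0.3, length.out = sizes[[s]])))
  item_bank(n_items = length(ids), m = length(tau), delta = delta, tau = tau,
            item_ids = ids,
            subscale_map = stats::setNames(subscales, ids))
}

#' Simulate burnout-questionnaire-like multidimensional responses
#'
#' Generates 23-item responses with a dominant general factor plus
#' subscale-specific person factors (a bifactor-style kernel), so that
#' within-subscale residual correlations exceed the local-dependency
#' critical value while between-subscale correlations do not -- the response
#' structure that motivates testlet analysis. Person covariates gender and
#' country form four equally sized strata; age is drawn around 41 years and
#' dichotomized at the sample median (ties to the lower group).
#'
#' @param n number of persons (default 2978, the complete-case count the
#'   generator emulates).
#' @param seed random seed (mandatory).
#' @param general_mean,general_sd distribution of the general burnout
#'   factor; defaults -1.04 and 1.045, matching the person distribution the
#'   generator emulates on the testlet metric.
#' @param subscale_sd standard deviation of the subscale-specific person
#'   factors (0 reduces the generator to a strictly unidimensional model).
#' @param bank generating \code{\link{item_bank}} (see
#'   \code{\link{bat_item_bank}}); DIF can be injected with
#'   \code{\link{inject_dif}}.
#' @return a \code{\link{response_matrix}} with person factors
#'   \code{gender}, \code{country}, \code{age}, \code{age_group}.
#' @export
sim_bat_like <- function(n = 2978, seed, general_mean = -1.04,
                         general_sd = 1.045, subscale_sd = 0.5,
                         bank = bat_item_bank()) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(bank$subscale_map)) stop("bank needs a subscale map")
  set.seed(seed)
  subscales <- unique(bank$subscale_map)
  # 2 x 2 equal strata: gender x country
  gender <- rep(c("M", "F"), length.out = n)
  country <- rep(c("NL", "FL", "FL", "NL"), length.out = n)
  age <- pmax(18, pmin(67, round(stats::rnorm(n, 41, 11))))
  age_group <- ifelse(age <= stats::median(age), "younger", "older")
  pf <- data.frame(gender = gender, country = country,
                   age = age, age_group = age_group,
                   stringsAsFactors = FALSE)
  g <- stats::rnorm(n, general_mean, general_sd)
  u <- matrix(stats::rnorm(n * length(subscales), 0, subscale_sd),
              n, length(subscales), dimnames = list(NULL, subscales))
  I <- length(bank$item_ids)
  scores <- matrix(0L, n, I, dimnames = list(NULL, bank$item_ids))
  # draw item by item at theta = general + own-subscale factor
  for (s in subscales) {
    member <- bank$item_ids[bank$subscale_map == s]
    sub_bank <- bank
    sub_bank$item_ids <- member
    sub_bank$beta <- bank$beta[member]
    sub_bank$dif <- bank$dif
    scores[, member] <- draw_responses(sub_bank, g + u[, s], pf)
  }
  response_matrix(scores, subscale_map = bank$subscale_map,
                  person_factors = pf, item_ids = bank$item_ids,
                  max_score = vapply(bank$beta, length, 1L))
}

#' Stratified subsampling of a response matrix
#'
#' Draws samples of a fixed size per stratum without replacement within each
#' draw, e.g. 200 respondents from each of the four gender-by-country strata
#' giving a subsample of 800, drawn twice for cross-validation.
#'
#' @param resp a \code{\link{response_matrix}} with the stratum variables in
#'   its person factors.
#' @param strata character vector of person-factor names defining strata.
#' @param k_per_stratum respondents drawn per stratum.
#' @param n_draws number of independent subsamples.
#' @param seed random seed.
#' @return a list of \code{n_draws} response matrices.
#' @export
stratified_subsample <- function(resp, strata = c("gender", "country"),
                                 k_per_stratum = 200, n_draws = 2, seed) {
  stopifnot(inherits(resp, "response_matrix"))
  if (missing(seed)) stop("seed is mandatory")
  pf <- resp$person_factors
  if (is.null(pf) || !all(strata %in% names(pf)))
    stop("person factors must contain: ", paste(strata, collapse = ", "))
  key <- interaction(pf[strata], drop = TRUE, sep = "/")
  sizes <- table(key)
  small <- names(sizes)[sizes < k_per_stratum]
  if (length(small))
    stop("stratum too small for k = ", k_per_stratum, ": ",
         paste(small, collapse = ", "))
  set.seed(seed)
  lapply(seq_len(n_draws), function(d) {
    idx <- sort(unlist(lapply(levels(key), function(lv)
      sample(which(key == lv), k_per_stratum))))
    response_matrix(resp$scores[idx, , drop = FALSE],
                    subscale_map = resp$subscale_map,
                    person_factors = pf[idx, , drop = FALSE],
                    item_ids = resp$item_ids,
                    max_score = resp$max_score)
  })
}
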