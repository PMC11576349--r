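#' Synthetic repertoire configuration
#'
#' Generative description of a synthetic paired repertoire: germline pools,
#' a correlated somatic-hypermutation model, a heavy-CDR3 length
#' distribution, and a VH-to-VL family pairing preference. Defaults are the
#' package's standard study conditions: mean per-chain mutation rate 5% of
#' chain length (about 6 mutations on a ~120-residue chain, a typical
#' memory-repertoire load), VH-VL mutation-count correlation 0.5 (the
#' magnitude observed in natural paired repertoires), pairing adherence
#' 0.9, and a CDR3 length jitter of up to +/-2 residues.
#'
#' Correlated counts use a shared latent gamma intensity: G ~ Gamma(a, a)
#' (mean 1), VH count ~ Poisson(mu_H G), VL count ~ Poisson(mu_L G)
#' conditionally independent. The shape `a` is solved analytically from the
#' target correlation (see [gamma_shape_for_rho()]); only positive target
#' correlations are achievable by this construction.
#'
#' @param germlines Germline pool tibble as [synthetic_germlines()].
#' @param mutation_rate_mean Mean per-chain mutation rate (fraction of
#'   chain length).
#' @param mutation_correlation Target Pearson correlation between VH and VL
#'   mutation counts, in (0, 1); 0 gives independent counts.
#' @param pairing_adherence Probability pi that a record's VL family is the
#'   preferred partner of its VH family (otherwise uniform over families).
#' @param pairing_rule Named character vector VH family -> preferred VL
#'   family.
#' @param cdr3_length_distribution Named numeric vector of probabilities
#'   over heavy-CDR3 length deltas (names are integer deltas).
#' @param fitness_noise_sd Gaussian noise added by
#'   [sample_fitness_dataset()].
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return An `fv_synth_config` list.
#' @export
synthetic_config <- function(germlines = synthetic_germlines(),
                             mutation_rate_mean = 0.05,
                             mutation_correlation = 0.5,
                             pairing_adherence = 0.9,
                             pairing_rule = c(SynVH1 = "SynVL1",
                                              SynVH2 = "SynVL2",
                                              SynVH3 = "SynVL3",
                                              SynVH4 = "SynVL4"),
                             cdr3_length_distribution = c("-2" = 0.05,
                                                          "-1" = 0.15,
                                                          "0" = 0.60,
                                                          "1" = 0.15,
                                                          "2" = 0.05),
                             fitness_noise_sd = 1,
                             seed = 0L) {
  stopifnot(nrow(germlines[germlines$chain == "VH", ]) > 0,
            nrow(germlines[germlines$chain == "VL", ]) > 0,
            mutation_rate_mean >= 0,
            pairing_adherence >= 0, pairing_adherence <= 1,
            abs(sum(cdr3_length_distribution) - 1) < 1e-8)
  if (mutation_correlation < 0 || mutation_correlation >= 1) {
    stop("mutation_correlation must be in [0, 1): the shared-gamma count ",
         "construction cannot produce negative correlations", call. = FALSE)
  }
  structure(list(
    germlines = germlines,
    mutation_rate_mean = mutation_rate_mean,
    mutation_correlation = mutation_correlation,
    pairing_adherence = pairing_adherence,
    pairing_rule = pairing_rule,
    cdr3_length_distribution = cdr3_length_distribution,
    fitness_noise_sd = fitness_noise_sd,
    seed = as.integer(seed)
  ), class = "fv_synth_config")
}

#' Gamma shape for a target count correlation
#'
#' For VH/VL counts that are conditionally Poisson with means `mu_h G` and
#' `mu_l G` given a shared G ~ Gamma(a, a), the marginal correlation is
#' `rho = (mu_h mu_l / a) / sqrt((mu_h + mu_h^2/a)(mu_l + mu_l^2/a))`.
#' This solves for `a` given `rho` (quadratic in `1/a`).
#'
#' @param rho Target correlation in (0, 1).
#' @param mu_h,mu_l Marginal mean counts.
#' @return The gamma shape `a` (Inf for `rho = 0`, i.e. independent
#'   Poisson).
#' @export
gamma_shape_for_rho <- function(rho, mu_h, mu_l) {
  if (rho == 0) return(Inf)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  # solve c^2 mu_h mu_l (1 - rho^2) - rho^2 (mu_h + mu_l) c - rho^2 = 0, c = 1/a
  A <- mu_h * mu_l * (1 - rho^2)
  B <- -rho^2 * (mu_h + mu_l)
  C <- -rho^2
  cc <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
  1 / cc
}

mutate_chain <- function(seq, n_sub) {
  n <- nchar(seq)
  n_sub <- min(n_sub, n)
  if (n_sub == 0L) return(list(seq = seq, pos = integer(0), new = character(0)))
  pos <- sort(sample.int(n, n_sub))
  chars <- strsplit(seq, "")[[1]]
  new <- vapply(pos, function(p) {
    sample(setdiff(AA_STANDARD, chars[p]), 1L)
  }, character(1))
  chars[pos] <- new
  list(seq = paste(chars, collapse = ""), pos = pos, new = new)
}

# apply a CDR3 length delta by inserting random residues at (or deleting
# around) the CDR3 midpoint; returns new seq and updated cdr3 end
apply_cdr3_delta <- function(seq, cdr3_start, cdr3_end, delta) {
  if (delta == 0L) return(list(seq = seq, cdr3_end = cdr3_end, inserted = character(0)))
  chars <- strsplit(seq, "")[[1]]
  mid <- cdr3_start + (cdr3_end - cdr3_start) %/% 2  # 0-based insertion point
  if (delta > 0) {
    ins <- sample(AA_STANDARD, delta, replace = TRUE)
    chars <- append(chars, ins, after = mid)
  } else {
    k <- min(-delta, cdr3_end - cdr3_start - 1L)
    if (k > 0) chars <- chars[-(mid + seq_len(k))]
    delta <- -k
    ins <- character(0)
  }
  list(seq = paste(chars, collapse = ""), cdr3_end = cdr3_end + delta,
       inserted = if (delta > 0) ins else character(0))
}

#' Simulate a synthetic paired repertoire
#'
#' Per record: draw a VH family uniformly and a VL family per the pairing
#' rule; draw correlated VH/VL substitution counts from the shared-gamma
#' model; substitute at uniformly chosen positions; jitter the heavy CDR3
#' length per the configured distribution; record every truth field. Fully
#' seeded: identical configs give identical corpora.
#'
#' @param config An [synthetic_config()].
#' @param n Number of paired records (>= 1).
#' @return Tibble with `id`, `heavy`, `light`, truth columns
#'   (`vh_germline`, `vl_germline`, `vh_mutations`, `vl_mutations`,
#'   `vh_cdr3_delta`, `boundary`, `family_pair_respected`), CDR annotation
#'   columns for both chains (`vh_cdr*`, `vl_cdr*`; 0-based half-open),
#'   and a `split` label (80/10/10 train/validation/test).
#' @export
sample_repertoire <- function(config, n) {
  stopifnot(inherits(config, "fv_synth_config"), n >= 1)
  gh <- config$germlines[config$germlines$chain == "VH", , drop = FALSE]
  gl <- config$germlines[config$germlines$chain == "VL", , drop = FALSE]
  mu_h <- config$mutation_rate_mean * mean(nchar(gh$seq))
  mu_l <- config$mutation_rate_mean * mean(nchar(gl$seq))
  a <- if (mu_h > 0 && mu_l > 0) {
    gamma_shape_for_rho(config$mutation_correlation, mu_h, mu_l)
  } else Inf
  deltas <- as.integer(names(config$cdr3_length_distribution))
  with_seed(config$seed, {
    vh_idx <- sample.int(nrow(gh), n, replace = TRUE)
    adhere <- stats::runif(n) < config$pairing_adherence
    preferred <- unname(config$pairing_rule[gh$name[vh_idx]])
    vl_name <- ifelse(adhere, preferred,
                      sample(gl$name, n, replace = TRUE))
    vl_idx <- match(vl_name, gl$name)
    G <- if (is.finite(a)) stats::rgamma(n, shape = a, rate = a) else rep(1, n)
    nh <- stats::rpois(n, mu_h * G)
    nl <- stats::rpois(n, mu_l * G)
    dH <- deltas[sample.int(length(deltas), n, replace = TRUE,
                            prob = config$cdr3_length_distribution)]
    if (config$mutation_rate_mean == 0) { nh[] <- 0L; nl[] <- 0L }
    rec <- vector("list", n)
    for (i in seq_len(n)) {
      h <- gh[vh_idx[i], ]
      l <- gl[vl_idx[i], ]
      hc <- apply_cdr3_delta(h$seq, h$cdr3_start, h$cdr3_end, dH[i])
      hm <- mutate_chain(hc$seq, nh[i])
      lm <- mutate_chain(l$seq, nl[i])
      rec[[i]] <- tibble::tibble(
        id = sprintf("synth%05d", i),
        heavy = hm$seq, light = lm$seq,
        vh_germline = h$name, vl_germline = l$name,
        vh_mutations = length(hm$pos), vl_mutations = length(lm$pos),
        vh_cdr3_delta = hc$cdr3_end - h$cdr3_end,
        boundary = nchar(hm$seq),
        family_pair_respected = vl_name[i] == preferred[i],
        vh_cdr1_start = h$cdr1_start, vh_cdr1_end = h$cdr1_end,
        vh_cdr2_start = h$cdr2_start, vh_cdr2_end = h$cdr2_end,
        vh_cdr3_start = h$cdr3_start, vh_cdr3_end = hc$cdr3_end,
        vl_cdr1_start = l$cdr1_start, vl_cdr1_end = l$cdr1_end,
        vl_cdr2_start = l$cdr2_start, vl_cdr2_end = l$cdr2_end,
        vl_cdr3_start = l$cdr3_start, vl_cdr3_end = l$cdr3_end,
        vh_sub_pos = list(hm$pos), vh_sub_new = list(hm$new),
        vl_sub_pos = list(lm$pos), vl_sub_new = list(lm$new),
        vh_cdr3_seq = list(substr(hc$seq, h$cdr3_start + 1L, hc$cdr3_end))
      )
    }
    out <- dplyr::bind_rows(rec)
    split <- rep("train", n)
    n_val <- floor(0.1 * n); n_test <- floor(0.1 * n)
    if (n_val + n_test > 0 && n > 2) {
      heldout <- sample.int(n, n_val + n_test)
      split[heldout[seq_len(n_val)]] <- "validation"
      if (n_test > 0) split[heldout[n_val + seq_len(n_test)]] <- "test"
    }
    out$split <- split
    out
  })
}

#' Simulate a fitness dataset for zero-shot evaluation
#'
#' Draws a repertoire and assigns each record a scalar fitness. By default
#' fitness is the negative total mutation load plus Gaussian noise (more
#' germline-like is fitter, giving zero-shot tests a recoverable signal);
#' when a model is supplied, fitness is negative perplexity plus noise,
#' for calibration tests.
#'
#' @param config An [synthetic_config()] (`fitness_noise_sd` sets the
#'   noise).
#' @param n Number of records (>= 3).
#' @param model Optional `fv_model` for perplexity-based fitness.
#' @return Tibble: `id`, `heavy`, `light`, `fitness`, `label`.
#' @export
sample_fitness_dataset <- function(config, n, model = NULL) {
  if (n < 3) stop("need at least 3 records", call. = FALSE)
  rep_ <- sample_repertoire(config, n)
  base <- if (is.null(model)) {
    -(rep_$vh_mutations + rep_$vl_mutations + abs(rep_$vh_cdr3_delta))
  } else {
    streams <- purrr::map2(rep_$heavy, rep_$light, encode_pair,
                           direction = "forward", vocab = model$vocab,
                           max_positions = model$config$max_positions)
    -perplexity(model, streams)
  }
  noise <- with_seed(config$seed + 17L,
                     stats::rnorm(n, 0, config$fitness_noise_sd))
  tibble::tibble(id = rep_$id, heavy = rep_$heavy, light = rep_$light,
                 fitness = base + noise,
                 label = if (is.null(model)) "neg_mutation_load" else "neg_perplexity")
}

#' Simulate developability flag annotations
#'
#' Draws per-antibody green/amber/red flags for the four structure-based
#' developability metrics (PSH, PPC, PNC, SFvCSP) with a configurable
#' green rate (amber and red share the remainder 2:1). These are synthetic
#' stand-ins for externally computed structure-based annotations.
#'
#' @param ids Character vector of antibody ids.
#' @param green_rate Per-metric probability of a green flag.
#' @param seed Integer seed.
#' @return Tibble: `id`, `psh`, `ppc`, `pnc`, `sfvcsp`.
#' @export
sample_flags <- function(ids, green_rate = 0.8, seed = 0L) {
  with_seed(seed, {
    draw <- function(n) sample(c("green", "amber", "red"), n, replace = TRUE,
                               prob = c(green_rate,
                                        2 * (1 - green_rate) / 3,
                                        (1 - green_rate) / 3))
    n <- length(ids)
    tibble::tibble(id = ids, psh = draw(n), ppc = draw(n), pnc = draw(n),
                   sfvcsp = draw(n))
  })
}
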