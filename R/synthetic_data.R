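# Synthetic study generator: an imbalanced two-class expression matrix with
# planted ground truth (informative genes, correlated redundant copies,
# tumor subtypes, subtype-dependent survival, subtype-enriched mutations and
# anti-correlated methylation), so every downstream stage can be verified
# without external data.
#
# Expression is log-normal: exp of a latent standard-Gaussian matrix, giving
# the non-negative right-skewed values the preprocessing stage assumes.
# Class and subtype shifts are planted additively on the observed scale in
# units of the within-class SD of the log-normal base (sqrt((e-1)e)), so
# "effect_size = 2" means a 2-SD class-mean separation as seen by any
# two-sample statistic. Redundant genes share their parent's latent Gaussian
# at the Pearson level rho_P = 2 sin(pi * rho_Spearman / 6) (the Gaussian
# rank-correlation identity; rank correlations survive exp()) and inherit an
# attenuated rho_P-scaled class shift, making them informative proxies.

#' Specify a synthetic imbalanced expression study
#'
#' Defaults emulate a liver-cancer-like cohort: a large tumor majority, a
#' small normal minority, a handful of truly informative genes plus
#' correlated redundant copies, three tumor subtypes with shifted marker
#' genes, subtype-dependent survival and subtype-enriched somatic mutations.
#'
#' @param n_genes total number of genes.
#' @param n_informative number of genes with a planted tumor/normal shift.
#' @param n_redundant number of noisy affine copies of informative genes.
#' @param n_major majority-class (tumor) sample count.
#' @param n_minor minority-class (normal) sample count; the imbalance
#'   direction is fixed, majority = tumor.
#' @param effect_size planted class-mean difference on the latent log scale,
#'   in units of the within-class standard deviation.
#' @param redundancy_rho target pairwise Spearman correlation between a
#'   redundant gene and its informative parent, in \[0, 1\].
#' @param n_subtypes number of planted tumor subtypes.
#' @param subtype_props mixing proportions of the subtypes (normalized to 1).
#' @param subtype_shift mean offset of a subtype's marker genes in its own
#'   subtype, same units as `effect_size` (default 3: strong, on/off-style
#'   subtype markers, so the planted partition is the unambiguous optimum).
#' @param n_subtype_genes marker genes planted per subtype.
#' @param hazard_ratios per-subtype relative hazards for survival times.
#' @param base_hazard baseline exponential hazard per day (default one event
#'   per two years for hazard ratio 1).
#' @param censoring_rate target fraction of censored samples under
#'   independent uniform censoring; 0 disables censoring.
#' @param n_mut_genes number of genes in the somatic mutation table.
#' @param n_enriched_mut_genes mutation genes with an elevated rate in one
#'   target subtype (assigned round-robin over subtypes).
#' @param background_mutation_rate per-gene per-sample Bernoulli rate outside
#'   the enriched subtype.
#' @param enriched_mutation_rate rate of an enriched gene inside its subtype.
#' @param meth_rho target Spearman correlation between methylation beta
#'   values and expression for coupled genes (negative: promoter-style
#'   repression).
#' @param n_meth_null number of additional genes given methylation data that
#'   is independent of expression.
#' @param dropout_rate probability that any expression entry is zeroed,
#'   emulating unexpressed measurements.
#' @param n_silent_genes genes that are mostly unexpressed (75% dropout),
#'   planted so the unexpressed-gene filter has work to do.
#' @param seed master RNG seed; every generator derives its own stream.
#' @return a validated `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_genes = 2000,
                           n_informative = 20,
                           n_redundant = 50,
                           n_major = 300,
                           n_minor = 40,
                           effect_size = 2,
                           redundancy_rho = 0.8,
                           n_subtypes = 3,
                           subtype_props = c(0.54, 0.21, 0.25),
                           subtype_shift = 3,
                           n_subtype_genes = 30,
                           hazard_ratios = c(1, 1, 3),
                           base_hazard = 1 / 730,
                           censoring_rate = 0.3,
                           n_mut_genes = 40,
                           n_enriched_mut_genes = 5,
                           background_mutation_rate = 0.05,
                           enriched_mutation_rate = 0.5,
                           meth_rho = -0.5,
                           n_meth_null = 10,
                           dropout_rate = 0.05,
                           n_silent_genes = 0,
                           seed = 1) {
  spec <- list(n_genes = n_genes, n_informative = n_informative,
               n_redundant = n_redundant, n_major = n_major,
               n_minor = n_minor, effect_size = effect_size,
               redundancy_rho = redundancy_rho, n_subtypes = n_subtypes,
               subtype_props = subtype_props / sum(subtype_props),
               subtype_shift = subtype_shift,
               n_subtype_genes = n_subtype_genes,
               hazard_ratios = hazard_ratios, base_hazard = base_hazard,
               censoring_rate = censoring_rate, n_mut_genes = n_mut_genes,
               n_enriched_mut_genes = n_enriched_mut_genes,
               background_mutation_rate = background_mutation_rate,
               enriched_mutation_rate = enriched_mutation_rate,
               meth_rho = meth_rho, n_meth_null = n_meth_null,
               dropout_rate = dropout_rate,
               n_silent_genes = n_silent_genes, seed = seed)
  validate_synthetic_spec(spec)
  structure(spec, class = "SyntheticSpec")
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    planted <- n_informative + n_redundant +
      n_subtypes * n_subtype_genes + n_silent_genes
    if (n_informative + n_redundant > n_genes) {
      stop("invalid spec: n_informative + n_redundant must be <= n_genes",
           call. = FALSE)
    }
    if (planted > n_genes) {
      stop("invalid spec: planted genes (informative + redundant + subtype ",
           "markers + silent) exceed n_genes", call. = FALSE)
    }
    if (n_minor < 2) stop("invalid spec: n_minor must be >= 2", call. = FALSE)
    if (n_major < n_minor) {
      stop("invalid spec: n_major must be >= n_minor ",
           "(the majority class is tumor)", call. = FALSE)
    }
    if (!is_prob(c(redundancy_rho, censoring_rate, dropout_rate,
                   background_mutation_rate, enriched_mutation_rate))) {
      stop("invalid spec: rates and probabilities must lie in [0, 1]",
           call. = FALSE)
    }
    if (length(hazard_ratios) != n_subtypes ||
        length(subtype_props) != n_subtypes) {
      stop("invalid spec: hazard_ratios and subtype_props must have length ",
           "n_subtypes", call. = FALSE)
    }
    if (any(hazard_ratios <= 0)) {
      stop("invalid spec: hazard_ratios must be positive", call. = FALSE)
    }
    if (abs(meth_rho) > 1) {
      stop("invalid spec: meth_rho must lie in [-1, 1]", call. = FALSE)
    }
  })
  invisible(spec)
}

# gene id layout: informative | redundant | subtype markers | silent | noise
synthetic_gene_layout <- function(spec) {
  ids <- sprintf("g%05d", seq_len(spec$n_genes))
  n_inf <- spec$n_informative
  n_red <- spec$n_redundant
  n_sub <- spec$n_subtypes * spec$n_subtype_genes
  informative <- ids[seq_len(n_inf)]
  redundant <- if (n_red > 0) ids[n_inf + seq_len(n_red)] else character(0)
  subtype <- if (n_sub > 0) ids[n_inf + n_red + seq_len(n_sub)]
             else character(0)
  silent <- if (spec$n_silent_genes > 0) {
    ids[n_inf + n_red + n_sub + seq_len(spec$n_silent_genes)]
  } else character(0)
  subtype_sets <- if (n_sub > 0) {
    split(subtype, rep(seq_len(spec$n_subtypes),
                       each = spec$n_subtype_genes))
  } else {
    stats::setNames(rep(list(character(0)), spec$n_subtypes),
                    seq_len(spec$n_subtypes))
  }
  list(ids = ids, informative = informative, redundant = redundant,
       subtype_sets = subtype_sets, silent = silent)
}

#' Generate a synthetic imbalanced expression matrix with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (a `GroundTruth` list: `informative_gene_ids`, `redundant_map`
#'   mapping each redundant gene to its informative parent,
#'   `subtype_of_sample` for tumor samples, `subtype_gene_sets`, and
#'   `enriched_mutation_genes` mapping mutation gene to target subtype).
#'   Deterministic given `spec$seed`.
#' @examples
#' sim <- generate_expression(synthetic_spec(n_genes = 100, n_major = 30,
#'                                           n_minor = 10, seed = 1))
#' dim(sim$matrix)
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  lay <- synthetic_gene_layout(spec)
  n_s <- spec$n_major + spec$n_minor
  sample_ids <- c(sprintf("T%04d", seq_len(spec$n_major)),
                  sprintf("N%04d", seq_len(spec$n_minor)))
  labels <- c(rep("tumor", spec$n_major), rep("normal", spec$n_minor))
  names(labels) <- sample_ids

  # within-class SD of the log-normal base exp(N(0,1))
  sd_base <- sqrt((exp(1) - 1) * exp(1))

  out <- with_seed(derive_seed(spec$seed, "expression"), {
    z <- matrix(stats::rnorm(spec$n_genes * n_s), nrow = spec$n_genes,
                dimnames = list(lay$ids, sample_ids))
    tumor_cols <- which(labels == "tumor")
    x <- exp(z)

    # subtype assignment
    subtype <- sample(seq_len(spec$n_subtypes), spec$n_major,
                      replace = TRUE, prob = spec$subtype_props)
    names(subtype) <- sample_ids[tumor_cols]

    # planted tumor/normal shift (effect_size within-class SDs on the
    # observed scale) for every informative gene, plus a subtype offset on
    # each gene's subtype block (round-robin) so subtypes are discoverable
    # from the selected panel, as in real tumor cohorts
    shift <- matrix(0, length(lay$informative), n_s,
                    dimnames = list(lay$informative, sample_ids))
    shift[, tumor_cols] <- spec$effect_size * sd_base
    inf_block <- stats::setNames(
      rep_len(seq_len(spec$n_subtypes), length(lay$informative)),
      lay$informative)
    for (s in seq_len(spec$n_subtypes)) {
      g <- names(inf_block)[inf_block == s]
      cols <- tumor_cols[subtype == s]
      if (length(g) && length(cols)) {
        shift[g, cols] <- shift[g, cols] + spec$subtype_shift * sd_base
      }
    }
    x[lay$informative, ] <- x[lay$informative, ] + shift

    # dedicated subtype marker genes (not tumor/normal informative): the
    # substrate for representative-gene recovery over all genes
    for (s in seq_len(spec$n_subtypes)) {
      g <- lay$subtype_sets[[s]]
      cols <- tumor_cols[subtype == s]
      if (length(g) && length(cols)) {
        x[g, cols] <- x[g, cols] + spec$subtype_shift * sd_base
      }
    }

    # redundant genes: share the parent's latent Gaussian at the Pearson
    # level matching the target Spearman, and inherit the parent's planted
    # shifts attenuated by that correlation: correlated informative proxies
    redundant_map <- character(0)
    if (spec$n_redundant > 0) {
      parents <- sample(lay$informative, spec$n_redundant, replace = TRUE)
      redundant_map <- stats::setNames(parents, lay$redundant)
      rho_p <- 2 * sin(pi * spec$redundancy_rho / 6)
      eps <- matrix(stats::rnorm(spec$n_redundant * n_s),
                    nrow = spec$n_redundant)
      x[lay$redundant, ] <- exp(rho_p * z[parents, , drop = FALSE] +
                                  sqrt(1 - rho_p^2) * eps) +
        rho_p * shift[parents, , drop = FALSE]
    }

    # dropout: uniformly at random, plus heavy dropout for silent genes
    if (spec$dropout_rate > 0) {
      drop <- matrix(stats::runif(length(x)) < spec$dropout_rate,
                     nrow = nrow(x))
      x[drop] <- 0
    }
    if (length(lay$silent)) {
      sil <- matrix(stats::runif(length(lay$silent) * n_s) < 0.75,
                    nrow = length(lay$silent))
      xs <- x[lay$silent, , drop = FALSE]
      xs[sil] <- 0
      x[lay$silent, ] <- xs
    }

    enriched <- character(0)
    if (spec$n_enriched_mut_genes > 0 && spec$n_mut_genes > 0) {
      enriched_ids <- sprintf("MUT%03d",
                              seq_len(min(spec$n_enriched_mut_genes,
                                          spec$n_mut_genes)))
      enriched <- stats::setNames(
        as.character(rep_len(seq_len(spec$n_subtypes),
                             length(enriched_ids))),
        enriched_ids)
    }
    list(x = x, subtype = subtype, redundant_map = redundant_map,
         inf_block = inf_block, enriched = enriched)
  })

  truth <- list(informative_gene_ids = lay$informative,
                redundant_map = out$redundant_map,
                informative_subtype_block = out$inf_block,
                subtype_of_sample = out$subtype,
                subtype_gene_sets = lay$subtype_sets,
                silent_gene_ids = lay$silent,
                enriched_mutation_genes = out$enriched)
  list(matrix = expression_matrix(out$x, labels = labels), truth = truth)
}

# Solve for the uniform-censoring horizon b so that the expected censored
# fraction over the subtype mixture matches the target rate:
# P(censor | hazard h) = P(U(0,b) < Exp(h)) = 1 - (1 - exp(-h b)) / (h b).
censoring_horizon <- function(spec) {
  hs <- spec$base_hazard * spec$hazard_ratios
  target <- spec$censoring_rate
  f <- function(b) {
    cens <- (1 - exp(-hs * b)) / (hs * b)
    sum(spec$subtype_props * cens) - target
  }
  stats::uniroot(f, lower = 1e-8 / spec$base_hazard,
                 upper = 1e8 / spec$base_hazard, tol = 1e-10)$root
}

#' Generate survival times for the planted subtypes
#'
#' Event times are exponential with per-subtype hazards
#' `base_hazard * hazard_ratios`; censoring is independent uniform on a
#' horizon solved so the expected censored fraction equals
#' `censoring_rate`.
#'
#' @param truth ground truth from [generate_expression()].
#' @param spec the matching [synthetic_spec()].
#' @return a `data.frame` with `sample_id`, `time_days`, `event`
#'   (1 = death, 0 = censored), one row per tumor sample.
#' @export
generate_survival <- function(truth, spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  st <- truth$subtype_of_sample
  if (is.null(st) || !length(st)) stop("no subtype assignments in `truth`",
                                       call. = FALSE)
  if (any(!st %in% seq_len(spec$n_subtypes))) {
    stop("unknown subtype in ground truth", call. = FALSE)
  }
  with_seed(derive_seed(spec$seed, "survival"), {
    h <- spec$base_hazard * spec$hazard_ratios[st]
    t_event <- stats::rexp(length(st), rate = h)
    if (spec$censoring_rate > 0) {
      b <- censoring_horizon(spec)
      cens <- stats::runif(length(st), 0, b)
      data.frame(sample_id = names(st),
                 time_days = pmin(t_event, cens),
                 event = as.integer(t_event <= cens),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = names(st), time_days = t_event,
                 event = 1L, stringsAsFactors = FALSE)
    }
  })
}

#' Generate a binary somatic-mutation matrix for the planted subtypes
#'
#' Every gene mutates at `background_mutation_rate`; each enriched gene is
#' raised to `enriched_mutation_rate`, but only in its target subtype.
#'
#' @inheritParams generate_survival
#' @return a binary matrix, mutation genes x tumor samples, class
#'   `MutationMatrix`.
#' @export
generate_mutations <- function(truth, spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  st <- truth$subtype_of_sample
  if (is.null(st) || !length(st)) stop("no subtype assignments in `truth`",
                                       call. = FALSE)
  genes <- sprintf("MUT%03d", seq_len(spec$n_mut_genes))
  with_seed(derive_seed(spec$seed, "mutations"), {
    p <- matrix(spec$background_mutation_rate, nrow = spec$n_mut_genes,
                ncol = length(st), dimnames = list(genes, names(st)))
    enr <- truth$enriched_mutation_genes
    for (g in names(enr)) {
      p[g, st == as.integer(enr[[g]])] <- spec$enriched_mutation_rate
    }
    m <- matrix(as.integer(stats::runif(length(p)) < p), nrow = nrow(p),
                dimnames = dimnames(p))
    structure(m, class = c("MutationMatrix", class(m)))
  })
}

#' Generate per-gene methylation beta values
#'
#' Informative and redundant genes receive methylation anti-correlated with
#' their expression at a target Spearman strength `meth_rho`
#' (promoter-methylation-style repression); `n_meth_null` noise genes
#' receive independent methylation, emulating genes whose methylation does
#' not track expression.
#'
#' @param m the [expression_matrix()] returned by [generate_expression()].
#' @inheritParams generate_survival
#' @return a beta-value matrix (genes x samples, values in (0, 1)) covering
#'   the coupled and null genes.
#' @export
generate_methylation <- function(m, truth, spec) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(spec, "SyntheticSpec"))
  coupled <- c(truth$informative_gene_ids, names(truth$redundant_map))
  noise_pool <- setdiff(rownames(m$values),
                        c(coupled, unlist(truth$subtype_gene_sets),
                          truth$silent_gene_ids))
  with_seed(derive_seed(spec$seed, "methylation"), {
    null_genes <- sample(noise_pool, min(spec$n_meth_null,
                                         length(noise_pool)))
    genes <- c(coupled, null_genes)
    n_s <- ncol(m$values)
    rho_p <- 2 * sin(pi * abs(spec$meth_rho) / 6)
    beta <- matrix(NA_real_, length(genes), n_s,
                   dimnames = list(genes, colnames(m$values)))
    for (g in genes) {
      # normal scores of the expression ranks; ties (dropout zeros) get
      # mid-ranks, preserving the Spearman target through the link
      zr <- stats::qnorm((rank(m$values[g, ]) - 0.5) / n_s)
      eps <- stats::rnorm(n_s)
      lat <- if (g %in% coupled) {
        sign(spec$meth_rho) * rho_p * zr + sqrt(1 - rho_p^2) * eps
      } else {
        eps
      }
      beta[g, ] <- stats::plogis(lat)
    }
    beta
  })
}
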