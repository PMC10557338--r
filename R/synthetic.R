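#' @title Seeded synthetic electropherogram generator
#' @name synthetic
#' @description
#' Generates every input the pipeline consumes, with full ground truth:
#' per-locus allele frequencies, Hardy-Weinberg diploid populations,
#' Mendelian families, and blood-meal peak tables combining mixture
#' proportions, a preservation-method height multiplier, sigmoid digestion
#' decay, lognormal height noise, amplicon-length-dependent dropout, the
#' homozygote peak-doubling rule and a detection threshold. Each sample draws
#' from its own RNG stream derived from the master seed by a fixed counter
#' scheme, so any subset regenerates identically.
NULL

#' Derive a child seed from a master seed and counter
#'
#' Linear-congruential mixing kept below 2^31 so the result is a valid
#' 32-bit seed for [set.seed()].
#'
#' @param seed Master integer seed.
#' @param counter Non-negative integer stream index.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 2147483647 * 1103515245 +
                as.numeric(counter) * 12345 + 12345) %% 2147483647)
}

#' Generator configuration
#'
#' Defaults are the calibrated study conditions the generator emulates:
#' heterozygote per-allele peaks near `base_height` RFU at time zero in
#' ethanol, lysis buffer boosting heights by the `preservation_multipliers`
#' ratio (2.2, i.e. 120% higher), digestion decay following the descending
#' sigmoid `1 / (1 + exp(k (t - t50)))` with `t50 = 55` h and `k = 0.15`/h,
#' multiplicative lognormal height noise, and a per-allele dropout
#' probability increasing with amplicon length on the logit scale (so the
#' longest amplicons, PentaD/PentaE/FGA, fail first).
#'
#' @param seed Master seed (all derived streams come from it).
#' @param n_alleles Alleles per locus (capped by each locus's range
#'   capacity), or a named per-locus vector.
#' @param freq_model `"dirichlet"` (flat Dirichlet by default) or
#'   `"uniform"` (equifrequent).
#' @param dirichlet_alpha Dirichlet concentration (default 1).
#' @param male_fraction Fraction of XY individuals (default 0.5).
#' @param detection_threshold Minimum reportable peak height, RFU.
#' @param base_height Mean heterozygote per-allele height at t = 0, ethanol.
#' @param height_sigma Lognormal sigma of multiplicative height noise.
#' @param preservation_multipliers Named multipliers; defaults
#'   `c(ethanol = 1, lysis_buffer = 2.2)`.
#' @param digestion List `A, t50, k` of the decay sigmoid.
#' @param base_dropout Per-allele dropout probability at `length_ref` bp.
#' @param length_dropout_slope Logit increase in dropout per bp above
#'   `length_ref`.
#' @param length_ref Reference amplicon length, bp.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_alleles = 6L,
                             freq_model = c("dirichlet", "uniform"),
                             dirichlet_alpha = 1,
                             male_fraction = 0.5,
                             detection_threshold = 50,
                             base_height = 300,
                             height_sigma = 0.3,
                             preservation_multipliers = c(ethanol = 1,
                                                          lysis_buffer = 2.2),
                             digestion = list(A = 1, t50 = 55, k = 0.15),
                             base_dropout = 0.002,
                             length_dropout_slope = 0.01,
                             length_ref = 100) {
  structure(list(seed = as.integer(seed), n_alleles = n_alleles,
                 freq_model = match.arg(freq_model),
                 dirichlet_alpha = dirichlet_alpha,
                 male_fraction = male_fraction,
                 detection_threshold = detection_threshold,
                 base_height = base_height, height_sigma = height_sigma,
                 preservation_multipliers = preservation_multipliers,
                 digestion = digestion, base_dropout = base_dropout,
                 length_dropout_slope = length_dropout_slope,
                 length_ref = length_ref),
            class = "generator_config")
}

# digestion decay factor in [0, 1]
.digestion_factor <- function(config, time_h) {
  d <- config$digestion
  d$A / (1 + exp(d$k * (time_h - d$t50)))
}

# per-allele dropout probability for a locus (worst-case amplicon length)
.dropout_prob <- function(config, size_max) {
  if (config$base_dropout <= 0) return(0)
  stats::plogis(stats::qlogis(config$base_dropout) +
                  config$length_dropout_slope * (size_max - config$length_ref))
}

# fragment size for an allele label at a panel row
.allele_size <- function(panel_row, allele) {
  if (isTRUE(panel_row$sex_marker)) {
    ifelse(allele == "Y", panel_row$size_max, panel_row$size_min)
  } else {
    panel_row$size_min + as.integer(allele) * panel_row$repeat_unit_len
  }
}

#' Generate per-locus allele frequencies for a panel
#'
#' Allele labels are repeat offsets drawn from each locus's range capacity
#' `(size_max - size_min) / repeat_unit_len + 1`; requesting more alleles
#' than the capacity is an error. Sex-marker loci get `{X, Y}` frequencies
#' implied by `male_fraction` (allele frequency of Y is half the male
#' fraction).
#'
#' @param panel An `str_panel`.
#' @param config A `generator_config`.
#' @return Named list: locus -> named numeric frequency vector summing to 1.
#' @export
gen_allele_freqs <- function(panel, config) {
  set.seed(derive_seed(config$seed, 1))
  out <- list()
  for (i in seq_len(nrow(panel))) {
    row <- panel[i, ]
    if (isTRUE(row$sex_marker)) {
      fy <- config$male_fraction / 2
      out[[row$locus]] <- c(X = 1 - fy, Y = fy)
      next
    }
    capacity <- (row$size_max - row$size_min) %/% row$repeat_unit_len + 1L
    n <- if (is.null(names(config$n_alleles))) config$n_alleles
         else config$n_alleles[[row$locus]]
    if (n > capacity)
      stop("locus ", row$locus, ": ", n, " alleles requested but size range",
           " only holds ", capacity)
    labels <- as.character(sort(sample.int(capacity, n) - 1L))
    f <- if (config$freq_model == "uniform") rep(1 / n, n)
         else { g <- stats::rgamma(n, shape = config$dirichlet_alpha); g / sum(g) }
    names(f) <- labels
    out[[row$locus]] <- f
  }
  out
}

# draw one diploid genotype list (locus -> 2 allele labels) from freqs
.draw_genotype <- function(freqs, male, sex_locus = "Amelogenin") {
  geno <- list()
  for (loc in names(freqs)) {
    if (loc %in% sex_locus) {
      geno[[loc]] <- if (male) c("X", "Y") else c("X", "X")
    } else {
      f <- freqs[[loc]]
      geno[[loc]] <- sample(names(f), 2, replace = TRUE, prob = f)
    }
  }
  geno
}

#' Generate a Hardy-Weinberg population of diploid profiles
#'
#' Genotypes are drawn independently per locus from the supplied allele
#' frequencies; sex-marker loci are X,X for females and X,Y for males, with
#' sex drawn at `male_fraction`. Each individual uses its own derived RNG
#' stream.
#'
#' @param freqs Output of [gen_allele_freqs()].
#' @param n Number of individuals (0 gives an empty list).
#' @param config A `generator_config`.
#' @param id_prefix Prefix for sample ids.
#' @return Named list of `str_profile` (heights absent).
#' @export
gen_population <- function(freqs, n, config, id_prefix = "IND") {
  if (n == 0) return(list())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, 1000 + i))
    male <- stats::runif(1) < config$male_fraction
    id <- sprintf("%s%03d", id_prefix, i)
    out[[i]] <- str_profile(id, .draw_genotype(freqs, male))
  }
  names(out) <- vapply(out, function(p) p$sample_id, character(1))
  out
}

#' Generate a Mendelian nuclear family
#'
#' Two unrelated parents drawn as in [gen_population()]; each child receives
#' one uniformly chosen allele from each parent per autosomal locus, and at
#' the sex marker the maternal X plus a paternal X or Y.
#'
#' @param freqs Output of [gen_allele_freqs()].
#' @param n_children Number of children (>= 1).
#' @param config A `generator_config`.
#' @param id_prefix Prefix for sample ids.
#' @param counter Family stream index (distinct families from one seed).
#' @return Named list of `str_profile`: `<prefix>_mother`, `<prefix>_father`,
#'   then `<prefix>_child<k>`.
#' @export
gen_family <- function(freqs, n_children, config, id_prefix = "FAM",
                       counter = 1) {
  stopifnot(n_children >= 1)
  base <- 200000 + counter * 100
  set.seed(derive_seed(config$seed, base))
  mother_g <- .draw_genotype(freqs, male = FALSE)
  father_g <- .draw_genotype(freqs, male = TRUE)
  kids <- vector("list", n_children)
  for (k in seq_len(n_children)) {
    set.seed(derive_seed(config$seed, base + k))
    geno <- list()
    for (loc in names(freqs)) {
      if (loc %in% "Amelogenin") {
        geno[[loc]] <- c("X", sample(father_g[[loc]], 1))
      } else {
        geno[[loc]] <- c(sample(mother_g[[loc]], 1), sample(father_g[[loc]], 1))
      }
    }
    kids[[k]] <- str_profile(sprintf("%s_child%d", id_prefix, k), geno)
  }
  out <- c(list(str_profile(paste0(id_prefix, "_mother"), mother_g),
                str_profile(paste0(id_prefix, "_father"), father_g)),
           kids)
  names(out) <- vapply(out, function(p) p$sample_id, character(1))
  out
}

#' Simulate the peak table of one blood meal
#'
#' For every contributor allele the expected height is the closed-form
#' product `base_height * proportion * preservation_multiplier *
#' digestion_factor(time_h) * (2 if the contributor is homozygous there)`,
#' multiplied by lognormal noise. Each allele copy-set then drops out with
#' the locus's length-dependent probability; surviving heights for the same
#' allele are summed across contributors into one peak, and peaks below the
#' detection threshold are removed. Every event is ledgered.
#'
#' @param contributors List of `str_profile` genotypes (1-3).
#' @param panel Panel the contributors are typed on.
#' @param config A `generator_config`.
#' @param time_h Post-feeding time, hours.
#' @param preservation Name into `config$preservation_multipliers`.
#' @param proportions Mixture proportions summing to 1 (default equal).
#' @param sample_id Blood-meal sample id.
#' @param counter Sample stream index.
#' @return List with `peaks` (`sample_id, multiplex, dye, size_bp, height`)
#'   and `ledger` (one row per contributor allele with `expected_height`,
#'   `noisy_height`, `dropped_out`, `below_threshold`; attributes `time_h`,
#'   `preservation`, `proportions`, `contributor_ids`).
#' @export
gen_bloodmeal <- function(contributors, panel, config, time_h = 0,
                          preservation = "lysis_buffer", proportions = NULL,
                          sample_id = "BM1", counter = 1) {
  k <- length(contributors)
  stopifnot(k >= 1, k <= 3)
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("gen_bloodmeal(): proportions must sum to 1")
  mult <- config$preservation_multipliers[[preservation]]
  if (is.null(mult)) stop("unknown preservation method: ", preservation)
  dig <- .digestion_factor(config, time_h)
  set.seed(derive_seed(config$seed, 500000 + counter))

  ledger <- list()
  for (j in seq_len(k)) {
    p <- contributors[[j]]
    for (loc in typed_loci(p)) {
      row <- panel[panel$locus == loc, ]
      if (nrow(row) == 0) next
      alleles <- p$calls[[loc]]$allele
      tab <- table(alleles)
      p_drop <- .dropout_prob(config, row$size_max)
      for (al in names(tab)) {
        zyg <- if (tab[[al]] == 2) "hom" else "het"
        expected <- config$base_height * proportions[j] * mult * dig *
          (if (zyg == "hom") 2 else 1)
        noise <- if (config$height_sigma > 0)
          exp(stats::rnorm(1, 0, config$height_sigma)) else 1
        dropped <- stats::runif(1) < p_drop
        ledger[[length(ledger) + 1]] <- data.frame(
          sample_id = sample_id, contributor = p$sample_id, locus = loc,
          allele = al, zygosity = zyg, proportion = proportions[j],
          multiplex = row$multiplex, dye = row$dye,
          size_bp = .allele_size(row, al),
          expected_height = expected, noisy_height = expected * noise,
          dropped_out = dropped, below_threshold = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  ledger <- if (length(ledger) > 0) do.call(rbind, ledger) else
    data.frame(sample_id = character(), contributor = character(),
               locus = character(), allele = character(),
               zygosity = character(), proportion = numeric(),
               multiplex = integer(), dye = character(), size_bp = numeric(),
               expected_height = numeric(), noisy_height = numeric(),
               dropped_out = logical(), below_threshold = logical())

  peaks <- data.frame(sample_id = character(), multiplex = integer(),
                      dye = character(), size_bp = numeric(),
                      height = numeric(), stringsAsFactors = FALSE)
  if (nrow(ledger) > 0) {
    live <- ledger[!ledger$dropped_out, , drop = FALSE]
    if (nrow(live) > 0) {
      agg <- stats::aggregate(noisy_height ~ locus + allele + multiplex +
                                dye + size_bp, data = live, FUN = sum)
      below <- agg$noisy_height < config$detection_threshold
      keyfun <- function(df) paste(df$locus, df$allele)
      ledger$below_threshold <- !ledger$dropped_out &
        keyfun(ledger) %in% keyfun(agg[below, , drop = FALSE])
      agg <- agg[!below, , drop = FALSE]
      if (nrow(agg) > 0) {
        peaks <- data.frame(sample_id = sample_id, multiplex = agg$multiplex,
                            dye = agg$dye, size_bp = agg$size_bp,
                            height = agg$noisy_height,
                            stringsAsFactors = FALSE)
        peaks <- peaks[order(peaks$multiplex, peaks$dye, peaks$size_bp), ]
        rownames(peaks) <- NULL
      }
    }
  }
  rownames(ledger) <- NULL
  attr(ledger, "time_h") <- time_h
  attr(ledger, "preservation") <- preservation
  attr(ledger, "proportions") <- proportions
  attr(ledger, "contributor_ids") <-
    vapply(contributors, function(p) p$sample_id, character(1))
  list(peaks = peaks, ledger = ledger)
}

#' Apply independent per-allele dropout to a genotype profile
#'
#' Each allele copy is removed with probability `rate`; loci losing both
#' copies become untyped. RNG state is the caller's (seed before calling for
#' reproducibility).
#'
#' @param profile An `str_profile`.
#' @param rate Per-allele dropout probability.
#' @return A thinned `str_profile`.
#' @export
drop_alleles <- function(profile, rate) {
  calls <- list()
  for (loc in typed_loci(profile)) {
    df <- profile$calls[[loc]]
    keep <- stats::runif(nrow(df)) >= rate
    if (any(keep)) calls[[loc]] <- df[keep, , drop = FALSE]
  }
  new_profile(profile$sample_id, calls)
}

#' Simulate a complete field study with ground truth
#'
#' Emulates the shape of the field trial: `n_mosquitoes` collected, of which
#' `n_with_human` contain human DNA (`n_double` double meals, `n_triple`
#' triple meals, the rest single), matched against a buccal-swab reference
#' database of `n_references` individuals of which a fraction
#' `frac_biters_referenced` of biters are members. Blood-meal post-feeding
#' times are uniform on `time_range`; double/triple meals draw a dominant
#' proportion in [0.70, 0.80] (consecutive feeds with unequal remaining
#' template). Mosquito-locus peaks for each mosquito's own genotype are
#' emitted alongside the human blood-meal peaks.
#'
#' @param config A `generator_config`.
#' @param n_mosquitoes Total collected (default 61).
#' @param n_references Reference individuals (default 40).
#' @param n_with_human Mosquitoes with human DNA (default 38).
#' @param n_double,n_triple Multi-feeding counts (defaults 4, 0).
#' @param frac_biters_referenced Probability a biter is drawn from the
#'   reference database rather than the unprofiled public (default 0.75).
#' @param time_range Post-feeding time range, hours (default c(0, 60)).
#' @param preservation Preservation method for all mosquitoes.
#' @return List with `panel` (bloodmeal layout), `references`,
#'   `mosquito_profiles`, `peaks` (all mosquitoes' combined human + mosquito
#'   peak table), `truth` (per-mosquito: contributors, times, proportions,
#'   session), `ledgers`, and `sessions`.
#' @export
gen_field_study <- function(config, n_mosquitoes = 61, n_references = 40,
                            n_with_human = 38, n_double = 4, n_triple = 0,
                            frac_biters_referenced = 0.75,
                            time_range = c(0, 60),
                            preservation = "lysis_buffer") {
  if (n_with_human > n_mosquitoes)
    stop("n_with_human exceeds n_mosquitoes")
  if (n_double + n_triple > n_with_human)
    stop("multi-feeding counts exceed mosquitoes with human DNA")
  panel <- load_panel("bloodmeal")
  human_freqs <- gen_allele_freqs(panel_subset(panel, "human"), config)
  mosq_freqs <- gen_allele_freqs(panel_subset(panel, "mosquito"), config)
  references <- gen_population(human_freqs, n_references, config,
                               id_prefix = "REF")
  # unprofiled public: biters that never gave a swab
  n_extra <- max(8, ceiling(n_with_human / 2))
  extras <- gen_population(human_freqs, n_extra, config, id_prefix = "EXT")
  mosquito_profiles <- gen_population(mosq_freqs, n_mosquitoes, config,
                                      id_prefix = "MOSQ")
  pool <- c(references, extras)
  pool_ref <- c(rep(TRUE, length(references)), rep(FALSE, length(extras)))

  n_contrib <- c(rep(3L, n_triple), rep(2L, n_double),
                 rep(1L, n_with_human - n_double - n_triple),
                 rep(0L, n_mosquitoes - n_with_human))
  set.seed(derive_seed(config$seed, 300000))
  n_contrib <- sample(n_contrib)   # shuffle over mosquitoes
  sessions <- stats::setNames(
    c(rep("S1", ceiling(n_mosquitoes / 2)),
      rep("S2", floor(n_mosquitoes / 2))),
    names(mosquito_profiles))

  peak_tables <- list()
  ledgers <- list()
  truth_rows <- list()
  for (i in seq_len(n_mosquitoes)) {
    mid <- names(mosquito_profiles)[i]
    set.seed(derive_seed(config$seed, 300000 + i))
    k <- n_contrib[i]
    contributors <- list()
    props <- numeric(0)
    time_h <- NA_real_
    if (k > 0) {
      referenced <- stats::runif(k) < frac_biters_referenced
      idx_pool <- which(pool_ref)
      idx_ext <- which(!pool_ref)
      picks <- integer(0)
      for (j in seq_len(k)) {
        from <- setdiff(if (referenced[j]) idx_pool else idx_ext, picks)
        picks <- c(picks, from[sample.int(length(from), 1)])
      }
      contributors <- pool[picks]
      time_h <- stats::runif(1, time_range[1], time_range[2])
      props <- if (k == 1) 1 else {
        p1 <- stats::runif(1, 0.70, 0.80)
        if (k == 2) c(p1, 1 - p1) else c(p1, (1 - p1) * 0.7, (1 - p1) * 0.3)
      }
      bm <- gen_bloodmeal(contributors, panel, config, time_h = time_h,
                          preservation = preservation, proportions = props,
                          sample_id = mid, counter = i)
      peak_tables[[length(peak_tables) + 1]] <- bm$peaks
      ledgers[[length(ledgers) + 1]] <- bm$ledger
    }
    # the mosquito's own DNA: full-strength, not digested with the meal
    own <- gen_bloodmeal(list(mosquito_profiles[[i]]), panel, config,
                         time_h = 0, preservation = preservation,
                         proportions = 1, sample_id = mid,
                         counter = 100000 + i)
    peak_tables[[length(peak_tables) + 1]] <- own$peaks
    truth_rows[[i]] <- data.frame(
      mosquito_id = mid, session = unname(sessions[mid]),
      n_contributors = k,
      contributors = paste(vapply(contributors, function(p) p$sample_id,
                                  character(1)), collapse = ";"),
      contributors_referenced = paste(
        vapply(contributors, function(p) p$sample_id %in% names(references),
               logical(1)), collapse = ";"),
      time_h = time_h,
      proportions = paste(signif(props, 6), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peak_tables)
  rownames(peaks) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(panel = panel, references = references,
       mosquito_profiles = mosquito_profiles, peaks = peaks, truth = truth,
       ledgers = ledgers, sessions = sessions)
}
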