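# Seeded synthetic generators. These emulate the *shape* of a curated ChEMBL
# IC50 extract and of PADEL-style fingerprint matrices -- planted-signal
# Bernoulli bit mixtures, not chemically realistic molecules -- so the whole
# pipeline can be exercised and benchmarked without downloads.

#' Fixture configuration for synthetic fingerprints
#'
#' Defaults emulate the study conditions of a curated GR-antagonist extract:
#' roughly 1:5 inactive:active imbalance, the five standard view widths
#' (fusion width 10,757), a background bit density of 0.30, and a planted
#' signal of 50 class-discriminative bits per view at densities 0.20
#' (active) vs 0.60 (inactive), blurred by 5% label-independent bit-flip
#' noise. At this signal level a classifier trained on the raw imbalanced
#' data ranks well but fails the minority class at the 0.5 threshold — the
#' imbalance pathology the resampling stage exists to fix — while the
#' balanced pipeline classifies nearly perfectly, so the benchmark exercises
#' the pipeline's value proposition rather than raw statistical power.
#'
#' @param n_active,n_inactive class sizes (defaults 500 / 100, ~1:5).
#' @param widths named per-view widths (default [view_widths()]).
#' @param density_base background Bernoulli bit density.
#' @param density_active,density_inactive densities on the signal bits.
#' @param signal_bits number of class-discriminative columns per view.
#' @param noise probability of flipping any bit after generation.
#' @param seed integer RNG seed.
#' @return named list of class `grq_fixture_config`.
#' @export
fixture_config <- function(n_active = 500, n_inactive = 100,
                           widths = view_widths(),
                           density_base = 0.30,
                           density_active = 0.20, density_inactive = 0.60,
                           signal_bits = 50, noise = 0.05, seed = 1) {
  stopifnot(density_base > 0, density_base < 1,
            density_active > 0, density_active < 1,
            density_inactive > 0, density_inactive < 1,
            signal_bits <= min(widths))
  structure(list(n_active = n_active, n_inactive = n_inactive, widths = widths,
                 density_base = density_base, density_active = density_active,
                 density_inactive = density_inactive, signal_bits = signal_bits,
                 noise = noise, seed = seed),
            class = "grq_fixture_config")
}

#' Generate a synthetic raw bioactivity table
#'
#' Draws IC50 values log-uniformly so that about `active_frac` of compounds
#' land above pIC50 6 and `intermediate_frac` land in the excluded 5-6 band,
#' and plants relation-symbol violations (censored `<`/`>` rows) and exact
#' duplicates so the curation filters have something to remove.
#'
#' @param n number of genuine compounds.
#' @param active_frac fraction with pIC50 > 6.
#' @param intermediate_frac fraction in the 5-6 band.
#' @param n_censored planted rows with non-`=` relation symbols.
#' @param n_duplicates planted exact duplicate rows.
#' @param seed integer RNG seed.
#' @return data.frame of raw rows (`compound_id`, `smiles`, `relation`,
#'   `ic50_nM`, `assay_type`) in randomized order.
#' @export
generate_bioactivity_table <- function(n, active_frac = 0.8,
                                       intermediate_frac = 0.05,
                                       n_censored = 5, n_duplicates = 3,
                                       seed = 1) {
  if (n < 1) stop("n must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  band <- sample(c("active", "intermediate", "inactive"), n, replace = TRUE,
                 prob = c(active_frac, intermediate_frac,
                          max(0, 1 - active_frac - intermediate_frac)))
  pic50 <- numeric(n)
  pic50[band == "active"] <- stats::runif(sum(band == "active"), 6.05, 9.5)
  pic50[band == "intermediate"] <- stats::runif(sum(band == "intermediate"), 5, 6)
  pic50[band == "inactive"] <- stats::runif(sum(band == "inactive"), 3, 4.95)
  ic50 <- 10^(9 - pic50)
  fake_smiles <- function(k) {
    vapply(seq_len(k), function(i) {
      paste0("C", paste(sample(c("C", "N", "O", "c1ccccc1", "Cl", "=O"),
                               sample(3:8, 1), replace = TRUE), collapse = ""))
    }, character(1))
  }
  rows <- data.frame(
    compound_id = sprintf("SYN%05d", seq_len(n)),
    smiles = fake_smiles(n),
    relation = "=",
    ic50_nM = ic50,
    assay_type = "IC50",
    stringsAsFactors = FALSE)
  if (n_censored > 0) {
    cens <- rows[sample.int(n, min(n_censored, n), replace = TRUE), , drop = FALSE]
    cens$compound_id <- sprintf("CEN%05d", seq_len(nrow(cens)))
    cens$relation <- sample(c("<", ">", "<=", ">="), nrow(cens), replace = TRUE)
    rows <- rbind(rows, cens)
  }
  if (n_duplicates > 0) {
    rows <- rbind(rows, rows[sample.int(n, min(n_duplicates, n)), , drop = FALSE])
  }
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Generate class-structured synthetic fingerprint views
#'
#' Per view, bits are independent Bernoulli draws at the background density;
#' the first `signal_bits` columns use the class-dependent densities instead,
#' planting a separable signal. Every bit is then flipped independently with
#' probability `noise`.
#'
#' @param cfg a [fixture_config()].
#' @return list with `views` (list of `grq_view`), `fused` (a `grq_fused`),
#'   and `labels` (character, `"active"`/`"inactive"`).
#' @export
generate_fingerprints <- function(cfg = fixture_config()) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_active + cfg$n_inactive
  labels <- c(rep("active", cfg$n_active), rep("inactive", cfg$n_inactive))
  views <- lapply(names(cfg$widths), function(nm) {
    w <- cfg$widths[[nm]]
    dens <- matrix(cfg$density_base, n, w)
    sig <- seq_len(cfg$signal_bits)
    dens[labels == "active", sig] <- cfg$density_active
    dens[labels == "inactive", sig] <- cfg$density_inactive
    m <- matrix(as.numeric(stats::runif(n * w) < dens), n, w)
    if (cfg$noise > 0) {
      flip <- matrix(stats::runif(n * w) < cfg$noise, n, w)
      m[flip] <- 1 - m[flip]
    }
    feature_view(nm, m, widths = cfg$widths)
  })
  list(views = views, fused = fuse_views(views, widths = cfg$widths), labels = labels)
}

#' Seeded synthetic fingerprint provider
#'
#' A [compute_view()] provider that hashes each compound key to a per-row
#' seed, so any subset of compounds gets reproducible fingerprints without
#' materializing the whole dataset.
#'
#' @param density bit density.
#' @param seed integer base seed.
#' @return provider function.
#' @export
synthetic_provider <- function(density = 0.3, seed = 1) {
  force(density); force(seed)
  function(ids, view, widths) {
    w <- widths[[view]]
    view_tag <- match(view, names(widths))
    out <- matrix(0, length(ids), w)
    if (!length(ids)) return(out)
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    for (i in seq_along(ids)) {
      h <- sum(utf8ToInt(as.character(ids[i])) * seq_along(utf8ToInt(as.character(ids[i]))))
      set.seed((seed * 97L + h * 13L + view_tag) %% .Machine$integer.max)
      out[i, ] <- as.numeric(stats::runif(w) < density)
    }
    out
  }
}
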