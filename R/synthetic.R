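# Seeded synthetic-data generators that emulate the statistical structure of
# each pipeline input, with ground-truth labels for recovery benchmarks.

#' Simulate a photo-cross-linking proteomics experiment
#'
#' Generates a proteinGroups-style entries tibble, its sample design and
#' per-protein truth labels under the +/-UV interactome design. Baseline
#' abundances are log-normal; each sample observation multiplies the
#' baseline by a condition effect (the enrichment factor for true
#' interactors in +UV samples, 1 otherwise) and log-normal replicate noise
#' with the given coefficient of variation. Abundance-dependent dropout
#' zeroes observations with logistic probability in log abundance (applied
#' after the condition effect, so exclusivity can arise both by construction
#' and stochastically). Proteins designated as exclusive binders are forced
#' to 0 in all -UV samples; contaminants and reverse-database decoys carry
#' the corresponding flags. Peptide sets are drawn per protein; a fraction
#' of background proteins is paired into shared-peptide families whose
#' shared fraction exceeds the 30% grouping threshold.
#'
#' @param n_background Proteins with no condition effect (default 800).
#' @param n_true_interactors Proteins enriched in +UV (default 50).
#' @param n_exclusive_plus Proteins forced absent from -UV (default 25).
#' @param n_contaminants,n_decoys Flagged entries (defaults 20 each).
#' @param enrichment_factor Linear +UV fold for true interactors (default 8).
#' @param abundance_log_mean,abundance_log_sd Natural-log parameters of the
#'   baseline log-normal abundance (defaults 16, 1.5).
#' @param noise_cv Replicate coefficient of variation (default 0.25).
#' @param dropout_midpoint Log-abundance at which dropout probability is
#'   50% (default `abundance_log_mean - 4.5`, i.e. three baseline SDs below
#'   the mean; set to `-Inf` to disable dropout).
#' @param dropout_slope Steepness of the logistic dropout curve (default 1).
#' @param peptides_per_protein Integer range (length 2) of peptides drawn
#'   per protein (default `c(5, 30)`).
#' @param shared_family_prob Probability that a background protein is paired
#'   into a shared-peptide family (default 0.05).
#' @param shared_fraction Fraction of the smaller peptide set shared within
#'   a designated family (default 0.5, above the 0.30 threshold).
#' @param n_replicates Replicates per condition (default 2).
#' @param seed Integer seed; the output is a pure function of the
#'   configuration and seed.
#' @return A list with elements `entries` (tibble accepted by the
#'   proteomics readers/writers), `design` (sample design tibble) and
#'   `truth` (tibble with `accession`, `class`, `true_fold`,
#'   `shared_partner`).
#' @export
simulate_proteomics <- function(n_background = 800, n_true_interactors = 50,
                                n_exclusive_plus = 25, n_contaminants = 20,
                                n_decoys = 20, enrichment_factor = 8,
                                abundance_log_mean = 16, abundance_log_sd = 1.5,
                                noise_cv = 0.25,
                                dropout_midpoint = abundance_log_mean - 4.5,
                                dropout_slope = 1,
                                peptides_per_protein = c(5, 30),
                                shared_family_prob = 0.05,
                                shared_fraction = 0.5,
                                n_replicates = 2, seed = 1) {
  if (enrichment_factor < 1) abort("enrichment_factor must be >= 1")
  if (noise_cv <= 0) abort("noise_cv must be > 0")
  counts <- c(n_background, n_true_interactors, n_exclusive_plus,
              n_contaminants, n_decoys)
  if (any(counts < 0)) abort("all counts must be >= 0")

  with_seed_or_current(seed, {
    classes <- rep(
      c("background", "true_interactor", "exclusive_plus", "contaminant", "decoy"),
      counts
    )
    n <- length(classes)
    accession <- sprintf("SIM%04d", seq_len(n))

    design <- tibble::tibble(
      sample_id = c(paste0("p", seq_len(n_replicates)),
                    paste0("m", seq_len(n_replicates))),
      condition = rep(c("plusUV", "minusUV"), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2)
    )

    log_a <- rnorm(n, abundance_log_mean, abundance_log_sd)
    true_fold <- ifelse(classes == "true_interactor", enrichment_factor, 1)
    sdlog <- sqrt(log(1 + noise_cv^2))

    ibaq <- matrix(0, nrow = n, ncol = nrow(design),
                   dimnames = list(NULL, design$sample_id))
    for (j in seq_len(nrow(design))) {
      f <- if (design$condition[j] == "plusUV") true_fold else rep(1, n)
      mu <- log_a + log(f)
      x <- exp(mu + rnorm(n, 0, sdlog))
      p_drop <- stats::plogis(dropout_slope * (dropout_midpoint - mu))
      x[runif(n) < p_drop] <- 0
      if (design$condition[j] == "minusUV") x[classes == "exclusive_plus"] <- 0
      ibaq[, j] <- x
    }

    # peptide sets, with designated sharing pairs among background proteins
    n_pep <- sample(peptides_per_protein[1]:peptides_per_protein[2], n,
                    replace = TRUE)
    peptides <- lapply(seq_len(n), function(i) {
      sprintf("PEP%04d_%02d", i, seq_len(n_pep[i]))
    })
    shared_partner <- rep(NA_character_, n)
    bg_idx <- which(classes == "background")
    if (length(bg_idx) >= 2 && shared_family_prob > 0) {
      paired <- bg_idx[runif(length(bg_idx)) < shared_family_prob]
      paired <- paired[seq_len(2 * (length(paired) %/% 2))]
      if (length(paired) >= 2) {
        first <- paired[seq(1, length(paired), by = 2)]
        second <- paired[seq(2, length(paired), by = 2)]
        for (k in seq_along(first)) {
          i <- first[k]; j <- second[k]
          n_share <- max(ceiling(shared_fraction * min(n_pep[i], n_pep[j])), 1)
          peptides[[j]][seq_len(n_share)] <- peptides[[i]][seq_len(n_share)]
          shared_partner[i] <- accession[j]
          shared_partner[j] <- accession[i]
        }
      }
    }

    entries <- tibble::tibble(
      protein_ids = accession,
      protein_name = paste("Simulated protein", accession),
      gene_symbol = paste0("SIMG", seq_len(n)),
      peptide_ids = peptides,
      contaminant = classes == "contaminant",
      reverse = classes == "decoy",
      only_by_site = FALSE
    )
    for (s in design$sample_id) entries[[ibaq_col(s)]] <- ibaq[, s]

    truth <- tibble::tibble(
      accession = accession,
      class = classes,
      true_fold = true_fold,
      shared_partner = shared_partner
    )
    list(entries = entries, design = design, truth = truth)
  })
}

#' Simulate an ITC isotherm
#'
#' Convenience wrapper around [simulate_isotherm()] with the default
#' bromodomain titration protocol.
#'
#' @inheritParams simulate_isotherm
#' @return An `itc_isotherm` tibble.
#' @export
simulate_itc <- function(params, protocol = itc_protocol(), noise_sd = 0,
                         seed = NULL) {
  simulate_isotherm(params, protocol, noise_sd = noise_sd, seed = seed)
}

#' Simulate colocalized peak sets and signal tracks
#'
#' Draws a latent list of genomic sites; each peak set independently
#' includes every latent site with its inclusion probability (so the
#' expected overlap fraction of set A against set B equals B's inclusion
#' probability when there are no private peaks), plus optional private
#' peaks placed uniformly. Each set's signal track is the sum of rectangular
#' bumps over its peaks plus Gaussian bin noise.
#'
#' @param chrom_lengths Named vector of chromosome lengths (default 1 Mb
#'   toy genome `c(chr1 = 1e6)`).
#' @param n_latent Number of latent shared sites (default 200).
#' @param include_prob Per-set latent-site inclusion probabilities; its
#'   length sets the number of peak sets (default `c(1, 0.5, 0.5)`).
#' @param n_private Private (set-specific) peaks per set (default 0).
#' @param peak_width Length-2 range of peak widths in bp (default
#'   `c(200, 500)`).
#' @param amplitude Length-2 range of bump heights (default `c(1, 5)`).
#' @param bin_size Track bin size in bp (default 50).
#' @param noise_sd Gaussian bin noise SD on tracks (default 0.1).
#' @param set_names Names for the sets (default `setA`, `setB`, ...).
#' @param seed Integer seed.
#' @return A list with `peaks` (named list of peaks tibbles), `tracks`
#'   (named list of [signal_track()]s) and `latent` (tibble of latent
#'   sites).
#' @export
simulate_peaks <- function(chrom_lengths = c(chr1 = 1e6), n_latent = 200,
                           include_prob = c(1, 0.5, 0.5), n_private = 0,
                           peak_width = c(200, 500), amplitude = c(1, 5),
                           bin_size = 50, noise_sd = 0.1,
                           set_names = paste0("set", LETTERS[seq_along(include_prob)]),
                           seed = 1) {
  if (any(include_prob < 0 | include_prob > 1)) {
    abort("include_prob entries must be in [0, 1]")
  }
  n_sets <- length(include_prob)
  with_seed_or_current(seed, {
    draw_intervals <- function(k) {
      chrom <- sample(names(chrom_lengths), k, replace = TRUE,
                      prob = chrom_lengths / sum(chrom_lengths))
      width <- sample(peak_width[1]:peak_width[2], k, replace = TRUE)
      start <- floor(runif(k) * (unname(chrom_lengths[chrom]) - width))
      tibble::tibble(chrom = chrom, start = start, end = start + width)
    }
    latent <- draw_intervals(n_latent)

    peaks <- vector("list", n_sets)
    for (i in seq_len(n_sets)) {
      inc <- runif(n_latent) < include_prob[i]
      p <- latent[inc, , drop = FALSE]
      if (n_private > 0) p <- dplyr::bind_rows(p, draw_intervals(n_private))
      peaks[[i]] <- dplyr::arrange(p, .data$chrom, .data$start)
    }
    names(peaks) <- set_names

    tracks <- lapply(peaks, function(p) {
      vals <- lapply(names(chrom_lengths), function(chrom) {
        n_bins <- ceiling(chrom_lengths[[chrom]] / bin_size)
        acc <- numeric(n_bins)
        sel <- p[p$chrom == chrom, , drop = FALSE]
        if (nrow(sel) > 0) {
          h <- runif(nrow(sel), amplitude[1], amplitude[2])
          for (k in seq_len(nrow(sel))) {
            b0 <- floor(sel$start[k] / bin_size) + 1
            b1 <- min(floor((sel$end[k] - 1) / bin_size) + 1, n_bins)
            acc[b0:b1] <- acc[b0:b1] + h[k]
          }
        }
        acc + rnorm(n_bins, 0, noise_sd)
      })
      names(vals) <- names(chrom_lengths)
      signal_track(vals, bin_size, chrom_lengths)
    })
    names(tracks) <- set_names
    list(peaks = peaks, tracks = tracks, latent = latent)
  })
}
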