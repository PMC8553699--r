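#' @importFrom rlang .data
#' @importFrom stats rnorm runif rbeta rgamma rbinom setNames
NULL

default_ancestries <- c("Mapuche", "Aymara", "European", "African")

# Dirichlet concentration calibrated so mean proportions match the cohort's
# global ancestry makeup (0.438 Mapuche / 0.026 Aymara / 0.521 European /
# 0.015 African); total concentration 20 keeps admixture homogeneous across
# individuals, with very few subjects beyond 80-90% of a single ancestry.
default_dirichlet <- 20 * c(0.438, 0.026, 0.521, 0.015)

#' Simulate a reference panel of ancestral allele frequencies
#'
#' Draws per-population alternate-allele frequencies under the
#' Balding-Nichols model: an ancestral frequency `p ~ Uniform(0.05, 0.95)`
#' per variant, and for each population with divergence `F` a frequency
#' `~ Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, so that
#' `E[freq] = p` and `Var[freq] = F p (1 - p)`.
#'
#' Variants are placed on one chromosome at evenly spaced physical
#' positions (1-based), with genetic positions from a uniform 1 cM/Mb map.
#' Ref/alt alleles are drawn from strand-unambiguous pairs.
#'
#' @param K Number of ancestral populations.
#' @param M Number of biallelic variants.
#' @param divergence Numeric vector of length `K`; per-population
#'   Balding-Nichols divergence values, all in (0, 1).
#' @param seed Integer RNG seed.
#' @param labels Ancestry names (length `K`).
#' @param spacing_bp Physical distance between adjacent variants, bp.
#' @param chrom Chromosome name for the simulated variants.
#' @return An object of class `reference_panel`: list with `K`, `labels`,
#'   `freqs` (K x M matrix), `variants` (tibble: chrom, pos, ref, alt, id)
#'   and `genetic_pos` (Morgans).
#' @export
simulate_reference_freqs <- function(K, M, divergence, seed = 1L,
                                     labels = NULL, spacing_bp = 1e5,
                                     chrom = "1") {
  if (length(K) != 1L || K < 1) stop("K must be a positive count")
  if (length(M) != 1L || M < 1) stop("M must be a positive count")
  divergence <- rep_len(divergence, K)
  if (any(divergence <= 0 | divergence >= 1)) {
    stop("divergence values must lie in (0, 1)")
  }
  if (is.null(labels)) {
    labels <- if (K == 4) default_ancestries else paste0("pop", seq_len(K))
  }
  stopifnot(length(labels) == K)
  set.seed(seed)
  p <- runif(M, 0.05, 0.95)
  freqs <- matrix(0, nrow = K, ncol = M, dimnames = list(labels, NULL))
  for (k in seq_len(K)) {
    f <- divergence[k]
    freqs[k, ] <- rbeta(M, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  # unambiguous ref/alt pairs only (no A/T, C/G)
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pick <- sample.int(nrow(pairs), M, replace = TRUE)
  pos <- spacing_bp * seq_len(M)  # double: can exceed .Machine$integer.max
  variants <- tibble::tibble(
    chrom = chrom,
    pos = pos,
    ref = pairs[pick, 1L],
    alt = pairs[pick, 2L],
    id = sprintf("v%06d", seq_len(M))
  )
  structure(
    list(K = as.integer(K), labels = labels, freqs = freqs,
         variants = variants, genetic_pos = pos * 1e-8,
         ancestral = p),
    class = "reference_panel"
  )
}

#' Simulate Dirichlet global ancestry proportions
#'
#' Each individual's admixture proportions are drawn from a Dirichlet
#' distribution. The default concentration is calibrated so cohort means
#' are approximately 0.438 Mapuche, 0.026 Aymara, 0.521 European and
#' 0.015 African.
#'
#' @param N Number of individuals.
#' @param dirichlet_params Positive concentration parameters (length K).
#' @param seed Integer RNG seed.
#' @param labels Ancestry names (length K).
#' @return A tibble with column `id` plus one proportion column per
#'   ancestry; rows sum to 1.
#' @export
simulate_admixture <- function(N, dirichlet_params = default_dirichlet,
                               seed = 1L, labels = NULL) {
  if (any(dirichlet_params <= 0)) stop("dirichlet_params must be positive")
  K <- length(dirichlet_params)
  if (is.null(labels)) {
    labels <- if (K == 4) default_ancestries else paste0("pop", seq_len(K))
  }
  stopifnot(length(labels) == K)
  set.seed(seed)
  g <- matrix(rgamma(N * K, shape = rep(dirichlet_params, each = N)),
              nrow = N, ncol = K)
  q <- g / rowSums(g)
  colnames(q) <- labels
  dplyr::bind_cols(tibble::tibble(id = sprintf("ind%05d", seq_len(N))),
                   tibble::as_tibble(q))
}

ancestry_matrix <- function(q) {
  m <- as.matrix(q[, setdiff(names(q), "id"), drop = FALSE])
  rownames(m) <- q$id
  m
}

#' Simulate local-ancestry tracts along the chromosome
#'
#' Each of an individual's two haplotypes follows a Markov chain over
#' ancestries: between adjacent variants at genetic distance `d` Morgans a
#' recombination-driven re-draw occurs with probability
#' `1 - exp(-generations * d)`, and a re-draw lands on ancestry `k` with
#' the individual's global proportion `q_k` (so `q` is the stationary
#' distribution). The local-ancestry dosage counts haplotypes carrying a
#' Native American label (Mapuche or Aymara).
#'
#' @param q Global-ancestry tibble from [simulate_admixture()].
#' @param panel A `reference_panel` (provides genetic positions).
#' @param generations Time since admixture, in generations (> 0).
#' @param seed Integer RNG seed.
#' @param native_labels Ancestries counted as Native American.
#' @return An object of class `local_ancestry`: list with `dosage`
#'   (N x M integer matrix in 0..2), `hap1`/`hap2` (N x M ancestry index
#'   matrices), `labels`, `ids`, and `n_switches` (per-haplotype re-draw
#'   counts, 2 columns).
#' @export
simulate_local_ancestry <- function(q, panel, generations = 15, seed = 1L,
                                    native_labels = c("Mapuche", "Aymara")) {
  if (generations <= 0) stop("generations must be positive")
  if (is.null(panel$genetic_pos)) stop("panel lacks genetic positions")
  qm <- ancestry_matrix(q)
  if (ncol(qm) != panel$K) stop("ancestry columns do not match panel K")
  N <- nrow(qm); M <- length(panel$genetic_pos); K <- panel$K
  d <- diff(panel$genetic_pos)
  switch_p <- 1 - exp(-generations * d)
  set.seed(seed)
  hap1 <- matrix(0L, N, M)
  hap2 <- matrix(0L, N, M)
  n_switches <- matrix(0L, N, 2L)
  idx_seq <- seq_len(M)
  for (i in seq_len(N)) {
    cq <- cumsum(qm[i, ])
    for (hp in 1:2) {
      renew <- c(TRUE, runif(M - 1L) < switch_p)
      # fresh ancestry draw available at every marker; used where renew
      draws <- findInterval(runif(M), cq) + 1L
      anc <- draws[cummax(idx_seq * renew)]
      if (hp == 1L) hap1[i, ] <- anc else hap2[i, ] <- anc
      n_switches[i, hp] <- sum(renew) - 1L
    }
  }
  native_idx <- which(colnames(qm) %in% native_labels)
  dosage <- matrix(as.integer(hap1 %in% native_idx), N, M) +
    matrix(as.integer(hap2 %in% native_idx), N, M)
  structure(
    list(dosage = dosage, hap1 = hap1, hap2 = hap2,
         labels = colnames(qm), ids = rownames(qm),
         native_labels = native_labels, n_switches = n_switches),
    class = "local_ancestry"
  )
}

#' Simulate diploid genotypes given local-ancestry tracts
#'
#' Each haplotype's allele at variant `m` is Bernoulli with the panel
#' frequency of that haplotype's ancestry at `m`; the genotype is the sum
#' over the two haplotypes. Missing genotypes are sprinkled uniformly at
#' `missing_rate`.
#'
#' @param panel A `reference_panel`.
#' @param la A `local_ancestry` object with haplotype labels.
#' @param missing_rate Probability a genotype call is missing.
#' @param seed Integer RNG seed.
#' @param sex Optional integer vector (0 male / 1 female); drawn
#'   Bernoulli(0.5) when omitted.
#' @return An object of class `cohort_genotypes`: list with `g` (N x M
#'   integer matrix, NA for missing), `variants`, `ids`, `sex`.
#' @export
simulate_genotypes <- function(panel, la, missing_rate = 0, seed = 1L,
                               sex = NULL) {
  N <- nrow(la$dosage); M <- ncol(la$dosage)
  if (M != ncol(panel$freqs)) stop("panel and local ancestry disagree on M")
  set.seed(seed)
  col_idx <- seq_len(M)
  g <- matrix(0L, N, M)
  for (i in seq_len(N)) {
    f1 <- panel$freqs[cbind(la$hap1[i, ], col_idx)]
    f2 <- panel$freqs[cbind(la$hap2[i, ], col_idx)]
    g[i, ] <- as.integer(runif(M) < f1) + as.integer(runif(M) < f2)
  }
  if (missing_rate > 0) {
    g[matrix(runif(N * M) < missing_rate, N, M)] <- NA_integer_
  }
  if (is.null(sex)) sex <- rbinom(N, 1L, 0.5)
  stopifnot(length(sex) == N)
  new_cohort_genotypes(g, panel$variants, la$ids, as.integer(sex))
}

new_cohort_genotypes <- function(g, variants, ids, sex) {
  stopifnot(nrow(g) == length(ids), ncol(g) == nrow(variants),
            length(sex) == length(ids))
  rownames(g) <- ids
  colnames(g) <- variants$id
  structure(list(g = g, variants = variants, ids = ids, sex = sex),
            class = "cohort_genotypes")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(sprintf("<cohort_genotypes> %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$g), ncol(x$g), 100 * mean(is.na(x$g))))
  invisible(x)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> K=%d (%s), %d variants\n",
              x$K, paste(x$labels, collapse = ", "), ncol(x$freqs)))
  invisible(x)
}

#' @export
print.local_ancestry <- function(x, ...) {
  cat(sprintf("<local_ancestry> %d samples x %d variants; Native = %s\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(x$native_labels, collapse = "+")))
  invisible(x)
}
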