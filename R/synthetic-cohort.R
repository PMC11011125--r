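#' Configuration for the synthetic bone-marrow cohort generator
#'
#' Parameters of the negative-binomial FPKM cohort simulator.  Defaults are
#' calibrated to a targeted 1408-gene panel profiled at roughly ten million
#' fragments per sample in a post-transplant cohort with 67% aGvHD
#' prevalence; see the methods vignette for the rationale behind each value.
#'
#' @param n_samples Number of samples (patients) to simulate.
#' @param n_genes Number of genes on the panel (default 1408).
#' @param n_informative Number of outcome-associated genes planted in the
#'   matrix (default 0, i.e. a global-null cohort).
#' @param effect_log2fc Log2 fold-change magnitude of every informative gene
#'   in cases versus controls; the sign of each gene's effect is drawn at
#'   random (default 1).
#' @param prevalence Case (event) probability per sample, strictly inside
#'   (0, 1); default 0.67.
#' @param dispersion Negative-binomial overdispersion shared by all genes
#'   (variance = mu + dispersion * mu^2); default 0.3.
#' @param libsize_range Length-2 vector, low <= high, of total sequenced
#'   fragments per sample; default `c(8e6, 12e6)`.
#' @param block_size Genes per correlated block for the Gaussian copula
#'   (default 40).
#' @param block_rho Within-block latent correlation in `[0, 1)`
#'   (default 0.2; set 0 for fully independent genes).
#' @param seed Master seed; every sub-draw uses a counter-derived stream.
#' @return An object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @examples
#' cohort_config(n_samples = 30, n_genes = 100)
#' @export
cohort_config <- function(n_samples,
                          n_genes = 1408L,
                          n_informative = 0L,
                          effect_log2fc = 1,
                          prevalence = 0.67,
                          dispersion = 0.3,
                          libsize_range = c(8e6, 12e6),
                          block_size = 40L,
                          block_rho = 0.2,
                          seed = 1L) {
  chk_count <- function(x, name, min = 1) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
      stop_config(sprintf("`%s` must be a single integer >= %s", name, min))
    }
  }
  chk_count(n_samples, "n_samples")
  chk_count(n_genes, "n_genes")
  chk_count(n_informative, "n_informative", min = 0)
  if (n_informative > n_genes) stop_config("`n_informative` must be <= `n_genes`")
  if (!is.numeric(effect_log2fc) || length(effect_log2fc) != 1 ||
    is.na(effect_log2fc) || effect_log2fc < 0) {
    stop_config("`effect_log2fc` must be a single non-negative number")
  }
  if (!is.numeric(prevalence) || length(prevalence) != 1 || is.na(prevalence) ||
    prevalence <= 0 || prevalence >= 1) {
    stop_config("`prevalence` must lie strictly inside (0, 1)")
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1 || is.na(dispersion) ||
    dispersion <= 0) {
    stop_config("`dispersion` must be a single positive number")
  }
  if (!is.numeric(libsize_range) || length(libsize_range) != 2 ||
    anyNA(libsize_range) || any(libsize_range <= 0) ||
    libsize_range[1] > libsize_range[2]) {
    stop_config("`libsize_range` must be two positive values with low <= high")
  }
  chk_count(block_size, "block_size")
  if (!is.numeric(block_rho) || length(block_rho) != 1 || is.na(block_rho) ||
    block_rho < 0 || block_rho >= 1) {
    stop_config("`block_rho` must lie in [0, 1)")
  }
  chk_count(seed, "seed", min = -Inf)
  structure(
    list(
      n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
      n_informative = as.integer(n_informative), effect_log2fc = effect_log2fc,
      prevalence = prevalence, dispersion = dispersion,
      libsize_range = libsize_range, block_size = as.integer(block_size),
      block_rho = block_rho, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a synthetic targeted-transcriptome cohort
#'
#' Generates a genes-by-samples FPKM matrix with the statistical structure a
#' targeted bone-marrow RNA panel analysis assumes: gene-specific baseline
#' abundances drawn log-normal (so FPKM spans decades), negative-binomial
#' fragment counts at per-sample library sizes, optional within-block
#' correlation through a Gaussian copula, and a planted set of
#' outcome-associated genes whose case-group count means are shifted by a
#' signed log2 fold-change before FPKM conversion.  The primary binary
#' endpoint (`agvhd`) is drawn at the configured prevalence and carries the
#' planted signal; a secondary endpoint (`alive`) is drawn independently at
#' the reference survival prevalence so four-way pipeline runs have a second
#' column to work with.
#'
#' @param config A [cohort_config()].
#' @param timepoint Label written into the sample metadata, `"post"`
#'   (default) or `"pre"`.
#' @param onset_median_day Median aGvHD onset day used for the cosmetic
#'   per-case onset draw (default 37.5).
#' @return An object of class `bm_cohort`: a list with
#'   \describe{
#'     \item{expression}{numeric FPKM matrix, `n_genes` rows x `n_samples`
#'       columns, gene/sample names set;}
#'     \item{counts}{the underlying fragment-count matrix;}
#'     \item{gene_lengths}{per-gene transcript length (bp);}
#'     \item{library_sizes}{per-sample total fragments;}
#'     \item{labels}{tibble `sample_id`, `timepoint`, `agvhd`, `alive`,
#'       `onset_day` (NA for controls);}
#'     \item{truth}{list with `informative_genes`, `per_gene_effect` (named,
#'       signed log2 fold-changes) and `case_assignment` — the ground-truth
#'       channel for parameter-recovery tests, never read by the pipeline;}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_samples = 24, n_genes = 60, seed = 7))
#' dim(cohort$expression)
#' @export
simulate_cohort <- function(config, timepoint = c("post", "pre"),
                            onset_median_day = 37.5) {
  if (!inherits(config, "cohort_config")) {
    stop_config("`config` must be created with cohort_config()")
  }
  timepoint <- match.arg(timepoint)
  G <- config$n_genes
  N <- config$n_samples
  gene_ids <- sprintf("G%0*d", max(4L, nchar(G)), seq_len(G))
  sample_ids <- sprintf("S%0*d", max(3L, nchar(N)), seq_len(N))

  # gene-level baselines: abundance (log-normal) and transcript length
  gene_par <- withr::with_seed(derive_seed(config$seed, 1L), {
    list(
      abundance = rlnorm(G, meanlog = 3, sdlog = 1.6),
      length_bp = round(exp(runif(G, log(500), log(10000))))
    )
  })

  case <- withr::with_seed(
    derive_seed(config$seed, 2L),
    rbinom(N, 1L, config$prevalence)
  )
  alive <- withr::with_seed(
    derive_seed(config$seed, 3L),
    rbinom(N, 1L, endpoint_prevalence("survival", "post"))
  )

  truth <- withr::with_seed(derive_seed(config$seed, 4L), {
    idx <- safe_sample(seq_len(G), config$n_informative)
    eff <- safe_sample(c(-1, 1), 0) # placeholder for empty case
    if (config$n_informative > 0) {
      eff <- sample(c(-1, 1), config$n_informative, replace = TRUE) *
        config$effect_log2fc
    }
    list(idx = idx, effect = eff)
  })

  libsize <- withr::with_seed(
    derive_seed(config$seed, 5L),
    as.integer(round(runif(N, config$libsize_range[1], config$libsize_range[2])))
  )

  # expected fragments per gene/sample: library size times the gene's share
  # of transcribed bases, case columns shifted by the planted fold-changes
  weight <- gene_par$abundance * gene_par$length_bp
  fc <- matrix(1, G, N)
  if (config$n_informative > 0) {
    fc[truth$idx, case == 1] <- 2^truth$effect
  }
  mu <- sweep(weight / sum(weight) * fc, 2L, libsize, `*`)

  # Gaussian copula: shared block factor + gene noise -> uniform quantiles
  U <- withr::with_seed(derive_seed(config$seed, 6L), {
    n_blocks <- ceiling(G / config$block_size)
    block_of <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(G)]
    z_block <- matrix(rnorm(n_blocks * N), n_blocks, N)
    z_gene <- matrix(rnorm(G * N), G, N)
    pnorm(sqrt(config$block_rho) * z_block[block_of, , drop = FALSE] +
      sqrt(1 - config$block_rho) * z_gene)
  })
  counts <- matrix(
    qnbinom(U, mu = mu, size = 1 / config$dispersion),
    G, N,
    dimnames = list(gene_ids, sample_ids)
  )

  fpkm <- counts * 1e9 / outer(gene_par$length_bp, as.numeric(libsize))
  dimnames(fpkm) <- dimnames(counts)

  labels <- tibble::tibble(
    sample_id = sample_ids,
    timepoint = timepoint,
    agvhd = as.integer(case),
    alive = as.integer(alive),
    onset_day = NA_real_
  )
  onset <- sample_onset_days(labels,
    median_day = onset_median_day,
    seed = derive_seed(config$seed, 7L)
  )
  labels$onset_day[match(onset$sample_id, labels$sample_id)] <- onset$onset_day

  structure(
    list(
      expression = fpkm,
      counts = counts,
      gene_lengths = stats::setNames(gene_par$length_bp, gene_ids),
      library_sizes = stats::setNames(libsize, sample_ids),
      labels = labels,
      truth = list(
        informative_genes = gene_ids[truth$idx],
        per_gene_effect = stats::setNames(truth$effect, gene_ids[truth$idx]),
        case_assignment = stats::setNames(
          ifelse(case == 1, "case", "control"), sample_ids
        )
      ),
      config = config
    ),
    class = "bm_cohort"
  )
}

#' @export
print.bm_cohort <- function(x, ...) {
  cat(sprintf(
    "<bm_cohort> %d genes x %d samples (FPKM), %d informative, prevalence %.2f, seed %d\n",
    nrow(x$expression), ncol(x$expression),
    length(x$truth$informative_genes),
    mean(x$labels$agvhd), x$config$seed
  ))
  invisible(x)
}

#' Convert fragment counts to FPKM
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `counts * 1e9 / (length_bp * total_fragments)`.
#'
#' @param counts Non-negative fragment counts, one per gene.
#' @param gene_lengths_bp Positive transcript lengths in base pairs, same
#'   length as `counts`.
#' @param total_fragments Single positive total fragment count for the
#'   sample.
#' @return Numeric vector of FPKM values.
#' @examples
#' fpkm_from_counts(100, 1000, 1e6) # 100
#' @export
fpkm_from_counts <- function(counts, gene_lengths_bp, total_fragments) {
  if (length(counts) != length(gene_lengths_bp)) {
    stop_domain("`counts` and `gene_lengths_bp` must have the same length")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop_domain("`counts` must be non-negative and complete")
  }
  if (anyNA(gene_lengths_bp) || any(gene_lengths_bp <= 0)) {
    stop_domain("`gene_lengths_bp` must be strictly positive")
  }
  if (length(total_fragments) != 1 || is.na(total_fragments) || total_fragments <= 0) {
    stop_domain("`total_fragments` must be a single strictly positive count")
  }
  counts * 1e9 / (gene_lengths_bp * total_fragments)
}

#' Draw aGvHD onset days for cases
#'
#' Cosmetic realism channel: onset days are drawn log-normal, parameterised
#' by the median (`exp(meanlog)`), for case samples only.  Controls receive
#' no onset day.
#'
#' @param labels Tibble with columns `sample_id` and `agvhd` (0/1).
#' @param median_day Positive median onset day (default 37.5).
#' @param sdlog Log-scale standard deviation of the onset distribution
#'   (default 0.5).
#' @param seed Seed for the draw.
#' @return Tibble `sample_id`, `onset_day`, one row per case (zero rows when
#'   there are no cases).
#' @examples
#' labs <- tibble::tibble(sample_id = c("a", "b"), agvhd = c(1, 0))
#' sample_onset_days(labs, seed = 1)
#' @export
sample_onset_days <- function(labels, median_day = 37.5, sdlog = 0.5, seed = 1L) {
  if (!is.data.frame(labels) || !all(c("sample_id", "agvhd") %in% names(labels))) {
    stop_domain("`labels` must contain `sample_id` and `agvhd` columns")
  }
  if (!is.numeric(median_day) || length(median_day) != 1 || median_day <= 0) {
    stop_domain("`median_day` must be a single positive number")
  }
  cases <- labels$sample_id[as_binary(labels$agvhd, "agvhd")]
  if (length(cases) == 0) {
    return(tibble::tibble(sample_id = character(), onset_day = numeric()))
  }
  days <- withr::with_seed(
    seed,
    rlnorm(length(cases), meanlog = log(median_day), sdlog = sdlog)
  )
  tibble::tibble(sample_id = cases, onset_day = days)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes `expression.tsv` (FPKM matrix), `labels.tsv` (sample metadata) and
#' `truth.tsv` (the ground-truth effect table, for audit only — the pipeline
#' never reads it) into `dir`.
#'
#' @param cohort A `bm_cohort` from [simulate_cohort()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "bm_cohort")) stop_domain("`cohort` must be a bm_cohort")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_expression_matrix(cohort$expression, paths[["expression"]])
  write_cohort_labels(cohort$labels, paths[["labels"]])
  truth <- tibble::tibble(
    gene_id = cohort$truth$informative_genes,
    log2fc = unname(cohort$truth$per_gene_effect)
  )
  readr::write_tsv(truth, paths[["truth"]])
  invisible(paths)
}
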