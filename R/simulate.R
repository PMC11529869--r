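# Mosaic-chromosome genotype simulator with two-population founders and a
# GCTA-style quantitative/binary trait generator.
#
# Founders are synthesized under the Balding-Nichols model (ancestral
# frequencies Uniform(0.05, 0.5); per-population frequencies
# Beta(p(1-F)/F, (1-p)(1-F)/F) at FST = F). Synthetic individuals are
# mosaics: the marker axis is cut into consecutive fixed-length segments and
# each individual copies every segment's dosages verbatim from one founder
# of its own population. Unrelated individuals draw each segment from any
# founder uniformly; related individuals draw only from a small ancestor
# subset shared within their sibship, so fewer ancestors means closer
# relatedness.

#' Specification of a simulated dataset
#'
#' @param n_founders Founder panel size (default 100).
#' @param n_samples Number of simulated individuals.
#' @param m_markers Number of markers.
#' @param segment_len Mosaic segment length in markers (default 2000; the
#'   last segment may be shorter).
#' @param n_populations 1 or 2 founder populations.
#' @param fst Balding-Nichols differentiation between populations, in
#'   `[0, 1)`.
#' @param related_fraction Fraction of individuals simulated as related.
#' @param ancestors_per_related Size of the ancestor subset a related
#'   sibship draws from (>= 1; smaller means closer relatedness).
#' @param sibship_size Number of related individuals sharing one ancestor
#'   subset (default 2).
#' @param n_causal Number of causal markers for the trait.
#' @param h2 Trait heritability in `[0, 1]`.
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @param prevalence Case fraction for binary traits, in `(0, 1)`.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @return A `simulation_spec`.
#' @export
simulation_spec <- function(n_founders = 100L, n_samples = 500L,
                            m_markers = 5000L, segment_len = 2000L,
                            n_populations = 2L, fst = 0.01,
                            related_fraction = 0, ancestors_per_related = 2L,
                            sibship_size = 2L,
                            n_causal = 25L, h2 = 0.5,
                            trait_kind = c("quantitative", "binary"),
                            prevalence = 0.1, seed = 1L) {
  trait_kind <- match.arg(trait_kind)
  spec <- list(n_founders = as.integer(n_founders),
               n_samples = as.integer(n_samples),
               m_markers = as.integer(m_markers),
               segment_len = as.integer(segment_len),
               n_populations = as.integer(n_populations),
               fst = fst, related_fraction = related_fraction,
               ancestors_per_related = as.integer(ancestors_per_related),
               sibship_size = as.integer(sibship_size),
               n_causal = as.integer(n_causal), h2 = h2,
               trait_kind = trait_kind, prevalence = prevalence,
               seed = as.integer(seed))
  if (spec$n_founders < 1L) stop("`n_founders` must be >= 1")
  if (spec$segment_len < 1L) stop("`segment_len` must be >= 1")
  if (!(spec$n_populations %in% 1:2)) stop("`n_populations` must be 1 or 2")
  if (!is.finite(spec$fst) || spec$fst < 0 || spec$fst >= 1) {
    stop("`fst` must lie in [0, 1)")
  }
  if (spec$related_fraction < 0 || spec$related_fraction > 1) {
    stop("`related_fraction` must lie in [0, 1]")
  }
  if (spec$ancestors_per_related < 1L) stop("`ancestors_per_related` must be >= 1")
  if (spec$related_fraction > 0 &&
      spec$ancestors_per_related > spec$n_founders) {
    stop("`ancestors_per_related` cannot exceed `n_founders`")
  }
  if (spec$n_causal > spec$m_markers) stop("`n_causal` cannot exceed `m_markers`")
  if (!is.finite(spec$h2) || spec$h2 < 0 || spec$h2 > 1) {
    stop("`h2` must lie in [0, 1]")
  }
  if (spec$prevalence <= 0 || spec$prevalence >= 1) {
    stop("`prevalence` must lie in (0, 1)")
  }
  structure(spec, class = "simulation_spec")
}

# run `expr` under a deterministic RNG substream, restoring caller state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.sim_stage_seed <- function(seed, stage) {
  ((seed %% .SKETCH_MOD) * 40503 + stage * 65537) %% .SKETCH_MOD
}

#' Synthesize a founder panel
#'
#' Draws ancestral allele frequencies `p ~ Uniform(0.05, 0.5)`, derives
#' per-population frequencies by the Balding-Nichols construction at the
#' spec's FST (identical populations at `fst = 0`), and samples founder
#' dosages `Binomial(2, p_pop)`. Founders are split evenly across
#' populations.
#'
#' @param spec A [simulation_spec()].
#' @return List with `dosages` (`n_founders x m` integer matrix),
#'   `p_anc`, `pop_freq` (`m x n_populations`), `population` (per founder).
#' @export
make_founders <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(.sim_stage_seed(spec$seed, 1L), {
    m <- spec$m_markers
    npop <- spec$n_populations
    p_anc <- stats::runif(m, 0.05, 0.5)
    pop_freq <- matrix(NA_real_, nrow = m, ncol = npop)
    for (k in seq_len(npop)) {
      pop_freq[, k] <- if (spec$fst == 0) p_anc else
        stats::rbeta(m,
                     p_anc * (1 - spec$fst) / spec$fst,
                     (1 - p_anc) * (1 - spec$fst) / spec$fst)
    }
    population <- sort(rep(seq_len(npop), length.out = spec$n_founders))
    dosages <- matrix(0L, nrow = spec$n_founders, ncol = m)
    for (i in seq_len(spec$n_founders)) {
      dosages[i, ] <- stats::rbinom(m, 2L, pop_freq[, population[i]])
    }
    list(dosages = dosages, p_anc = p_anc, pop_freq = pop_freq,
         population = population)
  })
}

#' Generate mosaic individuals from a founder panel
#'
#' Partitions the marker axis into consecutive segments of
#' `spec$segment_len` markers (last segment possibly shorter) and builds
#' each individual by copying every segment from a founder of its own
#' population. Unrelated individuals pick each segment's founder uniformly
#' at random; related individuals (the first `related_fraction` of each
#' population, grouped into sibships of `sibship_size`) pick only from
#' their sibship's ancestor subset of size `ancestors_per_related`. The
#' ledger records the source founder of every (individual, segment) pair,
#' so the mosaic can be replayed exactly.
#'
#' @param founders A [make_founders()] result.
#' @param spec The same [simulation_spec()].
#' @return List with `dosages` (`n_samples x m`), `ledger`
#'   (`n_samples x n_segments` founder indices), `population`, `related`,
#'   `sibship` (NA for unrelated), `segment_starts` (1-based).
#' @export
mosaic_individuals <- function(founders, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(.sim_stage_seed(spec$seed, 2L), {
    n <- spec$n_samples
    m <- spec$m_markers
    starts <- seq.int(1L, m, by = spec$segment_len)
    ends <- pmin(starts + spec$segment_len - 1L, m)
    nseg <- length(starts)

    population <- sort(rep(seq_len(spec$n_populations), length.out = n))
    related <- logical(n)
    sibship <- rep(NA_integer_, n)
    subsets <- list()
    sib_id <- 0L
    for (k in seq_len(spec$n_populations)) {
      members <- which(population == k)
      pool <- which(founders$population == k)
      if (length(pool) == 0L) pool <- seq_len(spec$n_founders)
      nrel <- round(spec$related_fraction * length(members))
      rel_members <- members[seq_len(nrel)]
      related[rel_members] <- TRUE
      if (nrel > 0L) {
        groups <- split(rel_members,
                        ceiling(seq_along(rel_members) / spec$sibship_size))
        for (g in groups) {
          sib_id <- sib_id + 1L
          sibship[g] <- sib_id
          subsets[[sib_id]] <- if (length(pool) <= spec$ancestors_per_related)
            pool else sample(pool, spec$ancestors_per_related)
        }
      }
    }

    ledger <- matrix(NA_integer_, nrow = n, ncol = nseg)
    dosages <- matrix(0L, nrow = n, ncol = m)
    for (i in seq_len(n)) {
      pool <- if (related[i]) subsets[[sibship[i]]]
              else which(founders$population == population[i])
      if (length(pool) == 0L) pool <- seq_len(spec$n_founders)
      src <- if (length(pool) == 1L) rep(pool, nseg)
             else sample(pool, nseg, replace = TRUE)
      ledger[i, ] <- src
      for (s in seq_len(nseg)) {
        rng <- starts[s]:ends[s]
        dosages[i, rng] <- founders$dosages[src[s], rng]
      }
    }
    list(dosages = dosages, ledger = ledger, population = population,
         related = related, sibship = sibship, segment_starts = starts)
  })
}

#' Simulate a quantitative or binary trait
#'
#' GCTA-style scheme: `n_causal` markers are chosen uniformly without
#' replacement among polymorphic markers; per-causal effects
#' `u_c ~ N(0, 1)` act on binomially normalized dosages
#' `w = (g - 2p)/sqrt(2p(1-p))`; environmental noise is drawn as
#' `e ~ N(0, var(g) (1 - h2)/h2)` so the realized heritability
#' `var(g)/var(y)` is centred on `h2`. At `h2 = 0` the genetic term is
#' dropped (`y` is pure standard-normal noise); at `h2 = 1` the noise is
#' zero. Binary traits threshold the liability at its empirical
#' `(1 - prevalence)` quantile, yielding exactly `floor(prevalence * n)`
#' cases.
#'
#' @param dosages `n x m` dosage matrix (from [mosaic_individuals()]).
#' @param spec The [simulation_spec()].
#' @return A `trait_truth` list: `causal_indices`, `effects`,
#'   `genetic_values`, `noise`, `liability`, `phenotype` (equals the
#'   liability for quantitative traits, 0/1 for binary), `realized_h2`.
#' @export
simulate_trait <- function(dosages, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(.sim_stage_seed(spec$seed, 3L), {
    n <- nrow(dosages)
    p <- colMeans(dosages) / 2
    poly <- which(p > 0 & p < 1)
    if (spec$n_causal > length(poly)) {
      stop(sprintf("n_causal = %d exceeds the %d polymorphic markers",
                   spec$n_causal, length(poly)))
    }
    causal <- sort(sample(poly, spec$n_causal))
    effects <- stats::rnorm(spec$n_causal)

    if (spec$h2 > 0) {
      W <- sweep(dosages[, causal, drop = FALSE], 2L, 2 * p[causal])
      W <- sweep(W, 2L, sqrt(2 * p[causal] * (1 - p[causal])), "/")
      g <- drop(W %*% effects)
      vg <- stats::var(g)
      noise <- if (spec$h2 >= 1) rep(0, n) else
        stats::rnorm(n, 0, sqrt(vg * (1 - spec$h2) / spec$h2))
    } else {
      g <- rep(0, n)
      noise <- stats::rnorm(n)
    }
    y <- g + noise
    vy <- stats::var(y)
    realized_h2 <- if (vy > 0) stats::var(g) / vy else 0

    phenotype <- y
    if (spec$trait_kind == "binary") {
      ncases <- floor(spec$prevalence * n)
      status <- integer(n)
      status[order(y, decreasing = TRUE)[seq_len(ncases)]] <- 1L
      phenotype <- status
    }
    structure(
      list(causal_indices = causal, effects = effects,
           genetic_values = g, noise = noise, liability = y,
           phenotype = phenotype, realized_h2 = realized_h2),
      class = "trait_truth")
  })
}

#' Simulate a complete dataset in memory
#'
#' Runs [make_founders()], [mosaic_individuals()] and [simulate_trait()]
#' for one spec. Deterministic: the same spec yields the same dataset.
#'
#' @param spec A [simulation_spec()].
#' @return List with `spec`, `founders`, `mosaic`, `truth`.
#' @export
simulate_dataset <- function(spec) {
  founders <- make_founders(spec)
  mosaic <- mosaic_individuals(founders, spec)
  truth <- simulate_trait(mosaic$dosages, spec)
  list(spec = spec, founders = founders, mosaic = mosaic, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Emits PLINK BED/BIM/FAM (FAM phenotype slot set to the missing code -9;
#' the phenotype ships separately), a whitespace-delimited phenotype file
#' (`FID IID TRAIT`), a causal-marker truth table, and optionally the
#' mosaic ledger. Files parse back via [open_bed()] to the same dosages.
#'
#' @param dosages `n x m` dosage matrix.
#' @param truth A `trait_truth` (or `NULL` to skip phenotype/truth files).
#' @param spec The [simulation_spec()].
#' @param prefix Output path stem.
#' @param ledger Optional mosaic ledger matrix to write as TSV.
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(dosages, truth, spec, prefix, ledger = NULL) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  variants <- data.frame(chrom = "1",
                         id = sprintf("snp%d", seq_len(m)),
                         cm = 0, bp = seq_len(m),
                         a1 = "A", a2 = "B",
                         stringsAsFactors = FALSE)
  samples <- data.frame(fid = sprintf("F%05d", seq_len(n)),
                        iid = sprintf("I%05d", seq_len(n)),
                        sex = 0L, pheno_slot = -9,
                        stringsAsFactors = FALSE)
  write_bed(dosages, variants, samples, prefix)
  files <- c(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
             fam = paste0(prefix, ".fam"))

  if (!is.null(truth)) {
    pheno <- data.frame(FID = samples$fid, IID = samples$iid,
                        TRAIT = truth$phenotype)
    ppath <- paste0(prefix, ".pheno.tsv")
    utils::write.table(pheno, ppath, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = TRUE)
    tpath <- paste0(prefix, ".truth.tsv")
    tt <- data.frame(index = truth$causal_indices,
                     id = variants$id[truth$causal_indices],
                     effect = truth$effects)
    utils::write.table(tt, tpath, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = TRUE)
    files <- c(files, pheno = ppath, truth = tpath)
  }
  if (!is.null(ledger)) {
    lpath <- paste0(prefix, ".ledger.tsv")
    utils::write.table(ledger, lpath, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    files <- c(files, ledger = lpath)
  }
  invisible(files)
}
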