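#' Configuration for a forward Wright-Fisher selection experiment
#'
#' Describes the whole simulated breeding design: a structured founder pool
#' with standing variation, one or more breeding lines under truncation
#' selection on an additive polygenic trait, scheduled line splits (e.g.
#' relaxation of selection), scheduled genotype sampling, and an optional
#' injected beneficial mutation.
#'
#' @param n_chr Number of chromosomes.
#' @param markers_per_chr Biallelic SNPs per chromosome, evenly spaced.
#' @param chr_length_cM,chr_length_bp Genetic and physical chromosome length
#'   (uniform recombination rate).
#' @param n_founder_sublines Partially differentiated founder sub-lines whose
#'   allele frequencies are mixed to form each line's founders.
#' @param founder_fst Differentiation of the founder sub-lines around the
#'   ancestral frequency (Balding-Nichols beta draws).
#' @param ancestral_freq_range Ancestral allele frequencies are uniform on
#'   this interval.
#' @param N Breeding population size per line per generation.
#' @param n_causal Number of additive causal loci behind the selected trait.
#' @param effect_sd SD of the causal-locus additive effects.
#' @param h2 Narrow-sense heritability in the founder generation (sets the
#'   environmental noise SD).
#' @param lines Named list of founding lines; each element is either
#'   `list(direction, prop)` (hermaphroditic truncation with proportion
#'   `prop` in (0, 1\]) or `list(direction, sires, dams)` (sex-structured
#'   breeding: the best `sires` males and `dams` females by trait are the
#'   parents, with family sizes equalized within each sex, as in managed
#'   poultry selection lines). `direction` is `"high"`, `"low"` or `"none"`.
#' @param splits Tibble with columns `source`, `generation`, `new_line`,
#'   `direction`, `prop`, and optionally `N` (census of the new line, at most
#'   the source's): at the stated absolute generation the new line is founded
#'   from the source line's current population (subsampled to `N`) and
#'   thereafter bred under its own selection mode.
#' @param sampling Tibble with columns `population` (output label), `line`,
#'   `generation` (absolute), `n`: genotype `n` individuals at that
#'   generation.
#' @param injection `NULL`, or `list(line, generation, chrom, effect)`: at
#'   the stated generation one allele copy at the injected marker (middle of
#'   `chrom`, held at frequency 0 in the founders) is placed in one random
#'   selected individual of `line`; the allele has additive trait effect
#'   `effect`.
#' @param n_generations Last generation to simulate (inferred from the
#'   schedule when `NULL`).
#' @param track_hz Record the per-generation mean true-frequency expected
#'   heterozygosity of every line.
#' @param track_freq Record full per-generation allele-frequency
#'   trajectories (memory-heavy; for small designs).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chr = 5, markers_per_chr = 2000,
                       chr_length_cM = 760, chr_length_bp = 1e8,
                       n_founder_sublines = 7, founder_fst = 0.2,
                       ancestral_freq_range = c(0.1, 0.9),
                       N = 50, n_causal = 25, effect_sd = 1, h2 = 0.5,
                       lines = list(HWS = list(direction = "high", prop = 0.2),
                                    LWS = list(direction = "low", prop = 0.2)),
                       splits = NULL, sampling = NULL, injection = NULL,
                       n_generations = NULL, track_hz = FALSE,
                       track_freq = FALSE, seed = NULL) {
  stopifnot(n_chr >= 1, markers_per_chr >= 2, N >= 2,
            founder_fst > 0, founder_fst < 1, h2 > 0, h2 <= 1)
  for (ln in lines) {
    stopifnot(ln$direction %in% c("high", "low", "none"))
    if (!is.null(ln$sires)) {
      stopifnot(ln$sires >= 1, ln$dams >= 1, ln$sires + ln$dams <= N)
    } else {
      stopifnot(ln$prop > 0, ln$prop <= 1)
    }
  }
  if (!is.null(splits)) splits <- tibble::as_tibble(splits)
  if (!is.null(sampling)) sampling <- tibble::as_tibble(sampling)
  gens <- c(if (!is.null(splits)) splits$generation,
            if (!is.null(sampling)) sampling$generation,
            if (!is.null(injection)) injection$generation)
  if (is.null(n_generations)) n_generations <- max(gens, 1)
  structure(list(n_chr = n_chr, markers_per_chr = markers_per_chr,
                 chr_length_cM = chr_length_cM, chr_length_bp = chr_length_bp,
                 n_founder_sublines = n_founder_sublines,
                 founder_fst = founder_fst,
                 ancestral_freq_range = ancestral_freq_range,
                 N = as.integer(N), n_causal = n_causal,
                 effect_sd = effect_sd, h2 = h2, lines = lines,
                 splits = splits, sampling = sampling, injection = injection,
                 n_generations = n_generations, track_hz = track_hz,
                 track_freq = track_freq, seed = seed),
            class = "sim_config")
}

sim_map <- function(cfg) {
  purrr::map_dfr(seq_len(cfg$n_chr), function(ch) {
    pos <- round(seq(1, cfg$chr_length_bp, length.out = cfg$markers_per_chr))
    tibble::tibble(marker_id = sprintf("c%d_m%04d", ch, seq_along(pos)),
                   chrom = as.character(ch), pos_bp = as.integer(pos),
                   pos_cM = (pos / cfg$chr_length_bp) * cfg$chr_length_cM,
                   allele_ref = "A", allele_alt = "C")
  })
}

line_freq <- function(pop) {  # true alt-allele frequency per marker
  unlist(lapply(pop, rowMeans), use.names = FALSE)
}

#' Run a forward Wright-Fisher simulation
#'
#' Founders are drawn by mixing the configured founder sub-line allele
#' frequencies (each founder haplotype comes from a random sub-line). Each
#' generation, trait values (additive genetic value + Gaussian environmental
#' noise) are computed and parents selected: either the top/bottom truncation
#' fraction (hermaphroditic lines) or the best sires and dams within each sex
#' (sex-structured lines). Offspring are produced by mating among the
#' selected parents avoiding selfing, with family sizes equalized across
#' parents (within each sex for sexed lines), and crossovers as a Poisson
#' process on the cM map (Haldane, no interference). Unselected lines
#' (`prop = 1`) mate as a plain Wright-Fisher population of size `N`
#' (effective size `N`). The injected mutation, if configured, replaces one
#' allele copy in one random breeding individual (a sire, in the sexed
#' scheme) at the stated generation. Fully reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @return A [gt_panel()] with one population per sampling event. Attributes:
#'   `truth` (injected-marker coordinates and the causal-locus table),
#'   `hz_trajectory` (if `track_hz`), `freq_trajectory` (if `track_freq`).
#' @export
simulate_lines <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  map <- sim_map(cfg)
  M <- nrow(map)
  chr_rows <- split(seq_len(M), factor(map$chrom, levels = unique(map$chrom)))
  cm <- lapply(chr_rows, function(r) map$pos_cM[r])
  N <- cfg$N

  # injected marker: middle of its chromosome, frequency 0 in founders
  inj_row <- NULL
  if (!is.null(cfg$injection)) {
    rows <- chr_rows[[as.character(cfg$injection$chrom)]]
    inj_row <- rows[ceiling(length(rows) / 2)]
  }

  # founder sub-line allele frequencies (Balding-Nichols around ancestral p)
  p0 <- stats::runif(M, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
  Fst <- cfg$founder_fst
  sub_freq <- vapply(seq_len(cfg$n_founder_sublines), function(s) {
    stats::rbeta(M, p0 * (1 - Fst) / Fst, (1 - p0) * (1 - Fst) / Fst)
  }, numeric(M))
  if (!is.null(inj_row)) sub_freq[inj_row, ] <- 0

  # causal loci
  pool <- setdiff(seq_len(M), inj_row)
  causal <- sort(sample(pool, min(cfg$n_causal, length(pool))))
  effects <- stats::rnorm(length(causal), 0, cfg$effect_sd)
  if (!is.null(inj_row)) {
    causal <- c(causal, inj_row)
    effects <- c(effects, cfg$injection$effect)
  }
  causal_tbl <- tibble::tibble(row = causal, marker_id = map$marker_id[causal],
                               chrom = map$chrom[causal],
                               pos_bp = map$pos_bp[causal], effect = effects)
  caus_by_chr <- lapply(chr_rows, function(r) which(causal %in% r))
  caus_local <- lapply(chr_rows, function(r) match(intersect(causal, r), r))

  new_founders <- function() {
    lapply(chr_rows, function(r) {
      sub <- sample.int(cfg$n_founder_sublines, 2 * N, replace = TRUE)
      f <- sub_freq[r, sub, drop = FALSE]
      h <- matrix(as.integer(stats::runif(length(f)) < f), nrow = length(r))
      h
    })
  }

  genetic_value <- function(pop) {
    n <- ncol(pop[[1]]) / 2
    gv <- numeric(n)
    for (ci in seq_along(chr_rows)) {
      loc <- caus_local[[ci]]
      if (!length(loc)) next
      eff <- effects[caus_by_chr[[ci]]]
      h <- pop[[ci]][loc, , drop = FALSE]
      dos <- h[, seq(1, 2 * n, 2), drop = FALSE] + h[, seq(2, 2 * n, 2), drop = FALSE]
      gv <- gv + as.numeric(crossprod(dos, eff))
    }
    gv
  }

  # line bookkeeping: each active line has a population and a generation
  st <- new.env()
  st$pops <- list(); st$mode <- list(); st$gen <- list(); st$N <- list()
  st$sex <- list()
  for (nm in names(cfg$lines)) {
    st$pops[[nm]] <- new_founders()
    st$mode[[nm]] <- cfg$lines[[nm]]
    st$gen[[nm]] <- 0
    st$N[[nm]] <- N
  }
  env_sd <- {
    g0 <- genetic_value(st$pops[[1]])
    s <- stats::sd(g0)
    if (!is.finite(s) || s == 0) 1 else s * sqrt((1 - cfg$h2) / cfg$h2)
  }

  hz_traj <- list(); freq_traj <- list()
  note_track <- function(nm) {
    if (cfg$track_hz || cfg$track_freq) {
      f <- line_freq(st$pops[[nm]])
      if (cfg$track_hz) {
        hz_traj[[length(hz_traj) + 1]] <<- tibble::tibble(
          line = nm, generation = st$gen[[nm]], mean_hz = mean(2 * f * (1 - f)))
      }
      if (cfg$track_freq) {
        freq_traj[[nm]] <<- rbind(freq_traj[[nm]], f)
      }
    }
  }
  for (nm in names(st$pops)) note_track(nm)

  samples <- list()
  take_samples <- function(nm) {
    if (is.null(cfg$sampling)) return(invisible())
    due <- cfg$sampling[cfg$sampling$line == nm &
                          cfg$sampling$generation == st$gen[[nm]], ]
    for (k in seq_len(nrow(due))) {
      ids <- sort(sample.int(st$N[[nm]], due$n[k]))
      dos <- do.call(rbind, lapply(st$pops[[nm]], function(h) {
        h[, 2 * ids - 1, drop = FALSE] + h[, 2 * ids, drop = FALSE]
      }))
      g <- t(dos)
      rownames(g) <- sprintf("%s_%02d", due$population[k], seq_len(due$n[k]))
      samples[[due$population[k]]] <<- g
    }
  }
  for (nm in names(st$pops)) take_samples(nm)

  # returns either a plain parent index vector (hermaphroditic mating) or
  # list(sires, dams) for a sex-structured line
  select_parents <- function(pop, mode, sex) {
    n <- ncol(pop[[1]]) / 2
    sexed <- !is.null(mode$sires)
    if (!sexed && mode$direction == "none" && mode$prop >= 1) return(seq_len(n))
    trait <- genetic_value(pop) + stats::rnorm(n, 0, env_sd)
    ord_of <- function(idx) switch(mode$direction,
                                   high = idx[order(trait[idx], decreasing = TRUE)],
                                   low = idx[order(trait[idx])],
                                   none = sample(idx))
    if (sexed) {
      males <- which(sex); females <- which(!sex)
      if (length(males) < mode$sires || length(females) < mode$dams) {
        stop("not enough candidates of one sex for the breeding scheme")
      }
      list(sires = sort(ord_of(males)[seq_len(mode$sires)]),
           dams = sort(ord_of(females)[seq_len(mode$dams)]))
    } else {
      n_sel <- max(2L, as.integer(round(mode$prop * n)))
      sort(ord_of(seq_len(n))[seq_len(n_sel)])
    }
  }

  # equalized allocation: each parent gets as near as possible the same
  # number of gamete slots (family-size equalization limits inbreeding)
  equal_slots <- function(parents, n_slots) {
    P <- length(parents)
    base <- n_slots %/% P
    slots <- c(rep(parents, base),
               if (n_slots - base * P > 0) parents[sample.int(P, n_slots - base * P)])
    sample(slots)
  }

  balanced_sex <- function(n) {
    sample(rep(c(TRUE, FALSE), length.out = n))
  }
  for (nm in names(st$pops)) st$sex[[nm]] <- balanced_sex(st$N[[nm]])

  for (gen in seq_len(cfg$n_generations)) {
    for (nm in names(st$pops)) {
      if (st$gen[[nm]] != gen - 1) next
      pop <- st$pops[[nm]]
      parents <- select_parents(pop, st$mode[[nm]], st$sex[[nm]])
      n_parents <- if (is.list(parents)) length(parents$sires) + length(parents$dams)
                   else length(parents)
      if (n_parents < 2) stop("fewer than 2 selected parents in line ", nm)
      if (!is.null(cfg$injection) && cfg$injection$line == nm &&
          cfg$injection$generation == gen - 1) {
        # the mutation enters through one breeding individual; in the sexed
        # scheme that is a sire (few sires x many offspring is what lets a
        # single new allele spread at the observed speed)
        pool <- if (is.list(parents)) parents$sires else parents
        carrier <- pool[sample.int(length(pool), 1)]
        ci <- as.character(cfg$injection$chrom)
        loc <- match(inj_row, chr_rows[[ci]])
        st$pops[[nm]][[ci]][loc, 2 * carrier - sample(0:1, 1)] <- 1L
        pop <- st$pops[[nm]]
      }
      Nl <- st$N[[nm]]
      if (is.list(parents)) {
        pa <- equal_slots(parents$sires, Nl)
        pb <- equal_slots(parents$dams, Nl)
      } else if (st$mode[[nm]]$prop < 1) {
        slots <- equal_slots(parents, 2 * Nl)
        pa <- slots[seq(1, 2 * Nl, 2)]
        pb <- slots[seq(2, 2 * Nl, 2)]
        for (i in which(pa == pb)) {  # resolve selfing by swapping partners
          j <- which(pb != pa[i] & pa != pb[i])[1]
          if (is.na(j)) next
          tmp <- pb[i]; pb[i] <- pb[j]; pb[j] <- tmp
        }
      } else {
        pa <- parents[sample.int(length(parents), Nl, replace = TRUE)]
        pb <- vapply(pa, function(a) {
          repeat {
            b <- parents[sample.int(length(parents), 1)]
            if (b != a) return(b)
          }
        }, numeric(1))
      }
      interleaved <- as.integer(rbind(pa, pb))
      st$pops[[nm]] <- lapply(seq_along(chr_rows), function(ci) {
        make_gametes(pop[[ci]], interleaved, cm[[ci]])
      })
      names(st$pops[[nm]]) <- names(chr_rows)
      st$gen[[nm]] <- gen
      st$sex[[nm]] <- balanced_sex(Nl)
      note_track(nm)
      take_samples(nm)
    }
    # line splits scheduled at this absolute generation
    if (!is.null(cfg$splits)) {
      due <- cfg$splits[cfg$splits$generation == gen, ]
      for (k in seq_len(nrow(due))) {
        src <- due$source[k]
        if (is.null(st$pops[[src]]) || st$gen[[src]] != gen) {
          stop("split source line ", src, " is not at generation ", gen)
        }
        nm2 <- due$new_line[k]
        N2 <- if ("N" %in% names(due) && !is.na(due$N[k])) due$N[k] else st$N[[src]]
        if (N2 > st$N[[src]]) stop("split line cannot exceed the source census")
        founders2 <- sort(sample.int(st$N[[src]], N2))
        cols <- as.integer(rbind(2 * founders2 - 1, 2 * founders2))
        st$pops[[nm2]] <- lapply(st$pops[[src]], function(h) h[, cols, drop = FALSE])
        st$mode[[nm2]] <- list(direction = due$direction[k], prop = due$prop[k])
        st$gen[[nm2]] <- gen
        st$N[[nm2]] <- N2
        st$sex[[nm2]] <- balanced_sex(N2)
        note_track(nm2)
        take_samples(nm2)
      }
    }
  }

  if (is.null(cfg$sampling) || !length(samples)) {
    stop("no sampling events produced any panel; check cfg$sampling")
  }
  panel <- gt_panel(map, samples[cfg$sampling$population[
    cfg$sampling$population %in% names(samples)]])
  attr(panel, "truth") <- list(
    injected = if (!is.null(inj_row)) {
      list(marker_id = map$marker_id[inj_row], chrom = map$chrom[inj_row],
           pos_bp = map$pos_bp[inj_row])
    },
    causal = causal_tbl)
  if (cfg$track_hz) attr(panel, "hz_trajectory") <- dplyr::bind_rows(hz_traj)
  if (cfg$track_freq) attr(panel, "freq_trajectory") <- freq_traj
  panel
}

default_design <- function(n_sample = 20, relaxed_N = 50) {
  list(
    splits = tibble::tibble(
      source = c("HWS", "LWS"), generation = 45,
      new_line = c("HWR", "LWR"), direction = "none", prop = 1,
      N = relaxed_N),
    sampling = tibble::tibble(
      population = c("HWS40", "LWS40", "HWS50", "LWS50", "HWS53", "LWS53",
                     "HWR9", "LWR9"),
      line = c("HWS", "LWS", "HWS", "LWS", "HWS", "LWS", "HWR", "LWR"),
      generation = c(40, 40, 50, 50, 53, 53, 54, 54),
      n = n_sample))
}

#' Canned simulation scenarios for the two-line design
#'
#' Ready-made [sim_config()]s reproducing the eight-subgroup design (high-
#' and low-selected lines sampled at generations 40, 50 and 53; relaxed
#' lines split off at generation 45 and sampled at their generation 9, i.e.
#' absolute generation 54; 20 individuals per sample), on a genetic map of
#' 5 x 760 cM (the chicken genome scale):
#'
#' * `A_drift_only` — no selection anywhere, census 50 per line, 10,000
#'   markers: the pure-drift null.
#' * `B_novel_mutation` — sex-structured truncation selection (best 20
#'   sires and 80 dams from a census of 250 per line) on the polygenic
#'   trait, 20,000 markers, plus one strongly beneficial mutation injected
#'   into a top sire of the high line at generation 42 (effect far above
#'   the phenotypic SD, so carriers are essentially always selected): the
#'   rapid-sweep scenario with onset in (40, 45\] and fixation in
#'   (45, 50\]. Relaxed lines are colonies of 50.
#' * `C_standing_sweeps` — the same breeding design with selection on
#'   standing variation only.
#' * `D_purging_relaxed` — as C, but after the split the relaxed lines are
#'   weakly counter-selected (truncation 0.5 in the opposite direction),
#'   emulating purging of previously favored alleles that carry a fitness
#'   cost once artificial selection stops.
#'
#' @param name Scenario name.
#' @param seed Seed stored in the config.
#' @param n_sample Individuals per sampled subgroup (default 20).
#' @return A [sim_config()].
#' @export
scenario_library <- function(name = c("A_drift_only", "B_novel_mutation",
                                      "C_standing_sweeps", "D_purging_relaxed"),
                             seed = NULL, n_sample = 20) {
  name <- match.arg(name)
  d <- default_design(n_sample)
  base <- list(splits = d$splits, sampling = d$sampling, seed = seed,
               n_generations = 54)
  sel <- list(HWS = list(direction = "high", sires = 20, dams = 80),
              LWS = list(direction = "low", sires = 20, dams = 80))
  drift <- list(HWS = list(direction = "none", prop = 1),
                LWS = list(direction = "none", prop = 1))
  cfg <- switch(
    name,
    A_drift_only = do.call(sim_config, c(base, list(N = 50, lines = drift))),
    B_novel_mutation = do.call(sim_config, c(base, list(
      N = 250, markers_per_chr = 4000, lines = sel, effect_sd = 2,
      injection = list(line = "HWS", generation = 42, chrom = 1, effect = 60)))),
    C_standing_sweeps = do.call(sim_config, c(base, list(
      N = 250, markers_per_chr = 4000, lines = sel, effect_sd = 2))),
    D_purging_relaxed = {
      d$splits$direction <- c("low", "high")  # counter-select the trait
      d$splits$prop <- 0.5
      do.call(sim_config, c(list(splits = d$splits, sampling = d$sampling,
                                 seed = seed, n_generations = 54),
                            list(N = 250, markers_per_chr = 4000,
                                 lines = sel, effect_sd = 2)))
    })
  cfg
}
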