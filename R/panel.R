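#' Genotype panel container
#'
#' A `gt_panel` bundles one shared marker map with one genotype matrix per
#' population. Genotypes are stored as alt-allele dosage (0, 1, 2) with `NA`
#' for missing calls; missing is never conflated with the homozygous
#' reference dosage 0. All populations in one panel are aligned to the same
#' marker map, sorted by (chromosome, position).
#'
#' @param map A tibble with columns `marker_id`, `chrom`, `pos_bp` and
#'   optionally `pos_cM`, `allele_ref`, `allele_alt`. Must be strictly sorted
#'   by (chrom, pos_bp) with no duplicated positions within a chromosome.
#' @param geno Named list of integer matrices (individuals x markers, values
#'   in 0/1/2 or `NA`), one per population; column count must equal
#'   `nrow(map)`.
#' @return An object of class `gt_panel`: a list with elements `map` (tibble)
#'   and `geno` (named list of matrices).
#' @examples
#' map <- tibble::tibble(marker_id = c("m1", "m2"), chrom = "1",
#'                       pos_bp = c(100L, 200L),
#'                       allele_ref = "A", allele_alt = "C")
#' g <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'             dimnames = list(c("i1", "i2"), c("m1", "m2")))
#' gt_panel(map, list(popA = g))
#' @export
gt_panel <- function(map, geno) {
  stopifnot(is.data.frame(map), is.list(geno), length(geno) >= 1)
  map <- tibble::as_tibble(map)
  req <- c("marker_id", "chrom", "pos_bp")
  if (!all(req %in% names(map))) {
    stop("marker map must have columns: ", paste(req, collapse = ", "))
  }
  validate_map(map)
  if (is.null(names(geno)) || any(names(geno) == "")) {
    stop("every genotype matrix must be named by its population id")
  }
  for (pop in names(geno)) {
    g <- geno[[pop]]
    if (!is.matrix(g) || ncol(g) != nrow(map)) {
      stop("genotype matrix for population '", pop,
           "' is not individuals x markers aligned to the map")
    }
    bad <- !(is.na(g) | g %in% 0:2)
    if (any(bad)) stop("non-missing genotype outside {0,1,2} in population '", pop, "'")
    storage.mode(geno[[pop]]) <- "integer"
    colnames(geno[[pop]]) <- map$marker_id
  }
  structure(list(map = map, geno = geno), class = "gt_panel")
}

validate_map <- function(map) {
  key <- split(map$pos_bp, map$chrom)
  for (ch in names(key)) {
    d <- diff(key[[ch]])
    if (any(d <= 0)) {
      i <- which(d <= 0)[1]
      off <- map$marker_id[map$chrom == ch][i + 1]
      stop("markers not strictly sorted by position on chromosome ", ch,
           " (offending marker: ", off, ")")
    }
  }
  # chromosome blocks must be contiguous
  r <- rle(as.character(map$chrom))
  if (anyDuplicated(r$values)) {
    stop("markers of one chromosome are not contiguous in the map")
  }
  if (all(c("allele_ref", "allele_alt") %in% names(map)) &&
      any(map$allele_ref == map$allele_alt)) {
    stop("allele_ref equals allele_alt for marker ",
         map$marker_id[which(map$allele_ref == map$allele_alt)[1]])
  }
  invisible(map)
}

#' @export
print.gt_panel <- function(x, ...) {
  cat("<gt_panel> ", nrow(x$map), " markers on ",
      length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  for (pop in names(x$geno)) {
    cat("  ", pop, ": ", nrow(x$geno[[pop]]), " individuals\n", sep = "")
  }
  invisible(x)
}

#' Population ids of a panel
#' @param panel A [gt_panel()].
#' @return Character vector of population ids.
#' @export
populations <- function(panel) names(panel$geno)

#' Read a genotype panel from PLINK ped/map or VCF
#'
#' Populations come from the PLINK family id column, or for VCF from a
#' `sample_pops` table. Only biallelic SNPs are accepted; markers must be
#' sorted by genome coordinate.
#'
#' @param path For `"pedmap"`, the common prefix of `<path>.ped` and
#'   `<path>.map` (or the full `.ped` path). For `"vcf"`, a VCF file path
#'   (plain text or bgzip).
#' @param format `"pedmap"` or `"vcf"`.
#' @param sample_pops For VCF input: a data frame with columns `sample_id`
#'   and `population` covering every sample in the file.
#' @return A [gt_panel()].
#' @export
read_panel <- function(path, format = c("pedmap", "vcf"), sample_pops = NULL) {
  format <- match.arg(format)
  if (format == "pedmap") read_pedmap(path) else read_vcf_panel(path, sample_pops)
}

read_pedmap <- function(prefix) {
  prefix <- sub("\\.ped$", "", prefix)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path) || !file.exists(map_path)) {
    stop("need both ", ped_path, " and ", map_path)
  }
  mp <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(mp) < 4) stop("map file must have 4 columns: chrom, id, cM, bp")
  map <- tibble::tibble(marker_id = mp[[2]], chrom = mp[[1]],
                        pos_bp = as.integer(mp[[4]]),
                        pos_cM = suppressWarnings(as.numeric(mp[[3]])))
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  n_mark <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_mark) {
    stop("ped file has ", ncol(ped), " columns; expected ", 6 + 2 * n_mark)
  }
  fam <- ped[[1]]
  iid <- ped[[2]]
  if (any(fam == "" | fam == "0")) {
    stop("sample without a population (family id) label: ",
         iid[which(fam == "" | fam == "0")[1]])
  }
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1, ncol(al), 2), drop = FALSE]
  a2 <- al[, seq(2, ncol(al), 2), drop = FALSE]
  known <- c("A", "C", "G", "T", "1", "2", "0")
  bad <- setdiff(unique(c(a1, a2)), known)
  if (length(bad)) stop("unknown allele code(s) in ped: ", paste(bad, collapse = ", "))
  # per-marker allele coding: ref = first non-missing allele seen, alt = other
  ref <- character(n_mark); alt <- character(n_mark)
  dosage <- matrix(NA_integer_, nrow(ped), n_mark)
  for (j in seq_len(n_mark)) {
    obs <- c(a1[, j], a2[, j])
    lev <- setdiff(sort(unique(obs)), "0")
    if (length(lev) > 2) {
      stop("marker ", map$marker_id[j], " has more than two alleles")
    }
    ref[j] <- if (length(lev) >= 1) lev[1] else "N"
    alt[j] <- if (length(lev) == 2) lev[2] else "N"
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    d[miss] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }
  map$allele_ref <- ref
  map$allele_alt <- ifelse(alt == "N", ".", alt)
  map$allele_alt[map$allele_alt == map$allele_ref] <- "."
  geno <- lapply(split(seq_len(nrow(ped)), fam), function(rows) {
    g <- dosage[rows, , drop = FALSE]
    rownames(g) <- iid[rows]
    g
  })
  gt_panel(map, geno)
}

read_vcf_panel <- function(path, sample_pops) {
  if (is.null(sample_pops)) {
    stop("VCF input needs a sample_pops table (sample_id, population)")
  }
  sample_pops <- tibble::as_tibble(sample_pops)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) > 1 |
    (nchar(fix[, "ALT"]) > 1 & fix[, "ALT"] != ".")
  if (any(multi)) {
    stop("non-biallelic-SNP site in VCF: ", fix[which(multi)[1], "ID"],
         " at ", fix[which(multi)[1], "CHROM"], ":", fix[which(multi)[1], "POS"])
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  map <- tibble::tibble(marker_id = ids, chrom = fix[, "CHROM"],
                        pos_bp = as.integer(fix[, "POS"]),
                        allele_ref = fix[, "REF"], allele_alt = fix[, "ALT"])
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samp <- colnames(gt)
  missing_pop <- setdiff(samp, sample_pops$sample_id)
  if (length(missing_pop)) {
    stop("sample without a population label: ", missing_pop[1])
  }
  dose <- function(s) {
    s <- sub(":.*", "", s)
    out <- rep(NA_integer_, length(s))
    out[s %in% c("0/0", "0|0")] <- 0L
    out[s %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[s %in% c("1/1", "1|1")] <- 2L
    known <- is.na(s) | s %in% c("0/0", "0|0", "0/1", "1/0", "0|1", "1|0",
                                 "1/1", "1|1", "./.", ".|.", ".")
    if (!all(known)) stop("unknown genotype code in VCF: ", s[!known][1])
    out
  }
  dosage <- vapply(seq_len(ncol(gt)), function(j) dose(gt[, j]),
                   integer(nrow(gt)))       # markers x samples
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1)
  dosage <- t(dosage)                       # samples x markers
  rownames(dosage) <- samp
  pop_of <- stats::setNames(sample_pops$population, sample_pops$sample_id)
  geno <- lapply(split(samp, pop_of[samp]), function(ss) {
    dosage[ss, , drop = FALSE]
  })
  gt_panel(map, geno)
}

#' Write a genotype panel to PLINK ped/map or VCF
#'
#' Round-trips exactly with [read_panel()]: calls, missingness and marker
#' order are preserved. VCF output is plain text.
#'
#' @param panel A [gt_panel()].
#' @param path Output prefix (pedmap) or file path (vcf).
#' @param format `"pedmap"` or `"vcf"`.
#' @return Invisibly, the path(s) written.
#' @export
write_panel <- function(panel, path, format = c("pedmap", "vcf")) {
  format <- match.arg(format)
  map <- panel$map
  ref <- if ("allele_ref" %in% names(map)) map$allele_ref else rep("A", nrow(map))
  alt <- if ("allele_alt" %in% names(map)) map$allele_alt else rep("C", nrow(map))
  alt[alt == "."] <- ref[alt == "."]  # monomorphic: write ref twice
  if (format == "pedmap") {
    path <- sub("\\.ped$", "", path)
    cm <- if ("pos_cM" %in% names(map)) map$pos_cM else 0
    cm[is.na(cm)] <- 0
    utils::write.table(
      data.frame(map$chrom, map$marker_id, cm, map$pos_bp),
      paste0(path, ".map"),
      quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
    con <- file(paste0(path, ".ped"), "w")
    on.exit(close(con))
    for (pop in names(panel$geno)) {
      g <- panel$geno[[pop]]
      for (i in seq_len(nrow(g))) {
        d <- g[i, ]
        a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, alt, ref))
        a2 <- ifelse(is.na(d), "0", ifelse(d == 2, alt, ref))
        writeLines(paste(c(pop, rownames(g)[i], "0", "0", "0", "-9",
                           as.vector(rbind(a1, a2))), collapse = " "), con)
      }
    }
    invisible(paste0(path, c(".ped", ".map")))
  } else {
    samples <- unlist(lapply(names(panel$geno), function(p) rownames(panel$geno[[p]])))
    gt <- do.call(rbind, panel$geno)        # all individuals x markers
    code <- matrix("./.", nrow(gt), ncol(gt))
    code[!is.na(gt) & gt == 0] <- "0/0"
    code[!is.na(gt) & gt == 1] <- "0/1"
    code[!is.na(gt) & gt == 2] <- "1/1"
    body <- vapply(seq_len(nrow(map)), function(j) {
      paste(c(map$chrom[j], map$pos_bp[j], map$marker_id[j], ref[j],
              if (alt[j] == ref[j]) "." else alt[j],
              ".", "PASS", ".", "GT", code[, j]), collapse = "\t")
    }, character(1))
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    writeLines(c(hdr, body), path)
    invisible(path)
  }
}

#' Sample-to-population table for a panel
#'
#' Convenience companion for VCF round-trips.
#' @param panel A [gt_panel()].
#' @return Tibble with columns `sample_id`, `population`.
#' @export
sample_populations <- function(panel) {
  purrr::map_dfr(names(panel$geno), function(p) {
    tibble::tibble(sample_id = rownames(panel$geno[[p]]), population = p)
  })
}

#' Remove markers with too many missing genotypes
#'
#' Missingness is counted across all individuals pooled over all populations
#' in the panel; markers with `max_missing` or more missing genotype calls
#' are dropped from every population and from the shared map.
#'
#' @param panel A [gt_panel()].
#' @param max_missing Markers with at least this many missing calls (pooled
#'   over all populations) are removed. Default 10.
#' @param quiet Suppress the retained/removed log message.
#' @return A list with elements `panel` (filtered [gt_panel()]) and `removed`
#'   (character vector of removed marker ids).
#' @export
qc_filter_missing <- function(panel, max_missing = 10, quiet = FALSE) {
  stopifnot(max_missing >= 0)
  n_miss <- Reduce(`+`, lapply(panel$geno, function(g) colSums(is.na(g))))
  drop <- n_miss >= max_missing
  removed <- panel$map$marker_id[drop]
  if (!quiet) {
    message("qc_filter_missing: removed ", sum(drop), " marker(s), retained ",
            sum(!drop))
  }
  if (!any(drop)) return(list(panel = panel, removed = character(0)))
  keep <- which(!drop)
  geno <- lapply(panel$geno, function(g) g[, keep, drop = FALSE])
  list(panel = gt_panel(panel$map[keep, ], geno), removed = removed)
}

#' Per-marker allele counts and major allele frequency
#'
#' Counts alt-allele copies over successfully called genotypes (two copies
#' per called individual). The major allele frequency `m` is
#' `max(n_alt, n_total - n_alt) / n_total`, in \[0.5, 1\]; it is `NA` where no
#' individual was called. The per-marker expected heterozygosity
#' `hz = 2 m (1 - m)` is included for convenience.
#'
#' @param panel A [gt_panel()].
#' @param population Population id(s) to tabulate; default all.
#' @return Tibble with columns `population`, `marker_id`, `chrom`, `pos_bp`,
#'   `n_alt`, `n_total`, `m`, `hz`, one row per population x marker.
#' @export
allele_counts <- function(panel, population = populations(panel)) {
  bad <- setdiff(population, populations(panel))
  if (length(bad)) stop("unknown population: ", paste(bad, collapse = ", "))
  purrr::map_dfr(population, function(pop) {
    g <- panel$geno[[pop]]
    n_called <- unname(colSums(!is.na(g)))
    n_alt <- unname(colSums(g, na.rm = TRUE))
    n_total <- 2L * n_called
    m <- ifelse(n_total > 0, pmax(n_alt, n_total - n_alt) / n_total, NA_real_)
    tibble::tibble(population = pop,
                   marker_id = panel$map$marker_id,
                   chrom = panel$map$chrom,
                   pos_bp = panel$map$pos_bp,
                   n_alt = as.integer(n_alt),
                   n_total = as.integer(n_total),
                   m = m,
                   hz = marker_het(m))
  })
}
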