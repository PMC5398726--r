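#' Digestion configuration
#'
#' Parameters of the in-silico proteolytic digestion used to enumerate
#' theoretically observable peptides. The default models a trypsin/Lys-C mix as
#' cleavage C-terminal to K or R, with the classical "no cleavage before
#' proline" exception applied to R only: Lys-C cleaves K-P bonds, so K sites
#' are kept even when followed by proline. Search-engine-style settings of 2
#' allowed missed cleavages and a minimum peptide length of 6 residues are the
#' defaults.
#'
#' @param enzyme `"trypsin_lysC"` (K/R sites, R-P suppressed) or `"trypsin"`
#'   (K/R sites, both K-P and R-P suppressed).
#' @param max_missed_cleavages Maximum internal cleavage sites a peptide may
#'   retain (>= 0).
#' @param min_peptide_length Minimum peptide length in residues (>= 1).
#' @param proline_exception Override of the enzyme's proline rule: which site
#'   residues are suppressed when followed by P. One of `"R"`, `"KR"`,
#'   `"none"`; default follows `enzyme`.
#' @return A list of class `digestion_config`.
#' @export
digestion_config <- function(enzyme = c("trypsin_lysC", "trypsin"),
                             max_missed_cleavages = 2L,
                             min_peptide_length = 6L,
                             proline_exception = NULL) {
  enzyme <- match.arg(enzyme)
  if (max_missed_cleavages < 0L) stop("max_missed_cleavages must be >= 0")
  if (min_peptide_length < 1L) stop("min_peptide_length must be >= 1")
  if (is.null(proline_exception))
    proline_exception <- if (enzyme == "trypsin_lysC") "R" else "KR"
  proline_exception <- match.arg(proline_exception, c("R", "KR", "none"))
  structure(list(enzyme = enzyme,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_peptide_length = as.integer(min_peptide_length),
                 proline_exception = proline_exception),
            class = "digestion_config")
}

#' Observability (scan-range) configuration
#'
#' Instrument settings that bound which peptides are detectable: the MS1 m/z
#' window and the precursor charge states admitted to fragmentation. Defaults
#' are an Orbitrap survey scan of 300-1800 m/z with charges 2-6.
#'
#' @param mz_min,mz_max MS1 scan range in m/z.
#' @param charge_min,charge_max Allowed precursor charge states.
#' @param proton_mass Proton mass in Da.
#' @return A list of class `observability_config`.
#' @export
observability_config <- function(mz_min = 300, mz_max = 1800,
                                 charge_min = 2L, charge_max = 6L,
                                 proton_mass = 1.00728) {
  if (!(mz_min < mz_max)) stop("mz_min must be < mz_max")
  if (!(charge_min >= 1L && charge_min <= charge_max))
    stop("need 1 <= charge_min <= charge_max")
  structure(list(mz_min = mz_min, mz_max = mz_max,
                 charge_min = as.integer(charge_min),
                 charge_max = as.integer(charge_max),
                 proton_mass = proton_mass),
            class = "observability_config")
}

# Monoisotopic residue masses (Da). C carries a fixed carbamidomethyl
# (+57.02146) because cysteines are alkylated with iodoacetamide upstream.
MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919 + 57.02146, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259,
  M = 131.04049, H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333,
  W = 186.07931)

WATER_MONO_MASS <- 18.0105646863

cleavage_sites <- function(sequence, cfg) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2L) return(integer())
  is_site <- res[-n] %in% c("K", "R")
  if (cfg$proline_exception != "none") {
    blocked <- res[-n] %in% strsplit(cfg$proline_exception, "")[[1]] &
      res[-1] == "P"
    is_site <- is_site & !blocked
  }
  which(is_site)  # cleavage after these positions
}

#' In-silico digest of a protein sequence
#'
#' Enumerates the peptides produced by the configured cleavage rule: every
#' contiguous stretch bounded by cleavage sites or by the protein termini,
#' retaining at most `max_missed_cleavages` internal sites and at least
#' `min_peptide_length` residues. Non-standard residues (B, Z, U, X, *) never
#' act as cleavage sites but are retained inside peptides.
#'
#' @param sequence Amino-acid string.
#' @param cfg A [digestion_config()].
#' @return data.frame with columns `peptide`, `start` (1-based position in the
#'   protein) and `missed_cleavages`, in N- to C-terminal order. Repeated
#'   peptide sequences at different positions are separate rows; callers that
#'   need the distinct-sequence set (emPAI counting) deduplicate `peptide`.
#' @export
digest <- function(sequence, cfg = digestion_config()) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  sites <- cleavage_sites(sequence, cfg)
  bounds <- c(0L, sites, nchar(sequence))   # fragment boundaries
  nfrag <- length(bounds) - 1L
  peps <- character(); starts <- integer(); missed <- integer()
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + cfg$max_missed_cleavages)
    for (j in i:jmax) {
      start <- bounds[i] + 1L
      end <- bounds[j + 1L]
      if (end - start + 1L < cfg$min_peptide_length) next
      peps <- c(peps, substr(sequence, start, end))
      starts <- c(starts, start)
      missed <- c(missed, j - i)
    }
  }
  data.frame(peptide = peps, start = starts, missed_cleavages = missed,
             stringsAsFactors = FALSE)
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus one water. Cysteine mass includes the fixed
#' carbamidomethyl modification. A residue without a mass entry (e.g. X, B, Z,
#' U) is an error naming the residue.
#'
#' @param peptides Character vector of peptide sequences.
#' @return Numeric vector of neutral masses in Da.
#' @export
peptide_mass <- function(peptides) {
  vapply(peptides, function(p) {
    res <- strsplit(p, "", fixed = TRUE)[[1]]
    m <- MONO_RESIDUE_MASS[res]
    if (anyNA(m))
      stop("no monoisotopic mass for residue(s): ",
           paste(unique(res[is.na(m)]), collapse = ", "))
    sum(m) + WATER_MONO_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Neutral-mass window implied by the scan range
#'
#' A peptide is observable if some allowed charge z puts its ion at
#' m/z = (M + z * proton) / z inside the scan range; equivalently its neutral
#' mass M lies between `mz_min * charge_min - charge_min * proton` and
#' `mz_max * charge_max - charge_max * proton`.
#'
#' @param cfg An [observability_config()].
#' @return Named numeric vector `c(min, max)` in Da.
#' @export
observable_mass_window <- function(cfg = observability_config()) {
  c(min = cfg$mz_min * cfg$charge_min - cfg$charge_min * cfg$proton_mass,
    max = cfg$mz_max * cfg$charge_max - cfg$charge_max * cfg$proton_mass)
}

observable_in_window <- function(mass, cfg) {
  # a peptide is observable if any allowed charge lands it in the scan range
  ok <- rep(FALSE, length(mass))
  for (z in cfg$charge_min:cfg$charge_max) {
    mz <- (mass + z * cfg$proton_mass) / z
    ok <- ok | (mz >= cfg$mz_min & mz <= cfg$mz_max)
  }
  ok
}

#' Count observable peptides of a protein
#'
#' Number of distinct peptide sequences from [digest()] whose neutral
#' monoisotopic mass is observable at some allowed charge within the scan
#' range. This is the emPAI denominator N_observable.
#'
#' @param sequence Amino-acid string.
#' @param dcfg A [digestion_config()].
#' @param ocfg An [observability_config()].
#' @return Integer count.
#' @export
count_observable <- function(sequence, dcfg = digestion_config(),
                             ocfg = observability_config()) {
  peps <- unique(digest(sequence, dcfg)$peptide)
  if (!length(peps)) return(0L)
  sum(observable_in_window(peptide_mass(peps), ocfg))
}

#' emPAI score
#'
#' The exponentially modified protein abundance index,
#' `10^(n_observed / n_observable) - 1`, a spectral-count proxy for molar
#' protein abundance. Vectorised. `n_observed = 0` yields 0; a protein with
#' observed peptides but zero observable peptides is an error.
#'
#' @param n_observed Distinct observed peptides per protein.
#' @param n_observable Distinct observable peptides per protein.
#' @return Numeric emPAI score(s).
#' @export
empai_score <- function(n_observed, n_observable) {
  if (any(n_observed < 0) || any(n_observable < 0))
    stop("counts must be non-negative")
  bad <- n_observable == 0 & n_observed > 0
  if (any(bad))
    stop("n_observable = 0 with n_observed > 0: protein is unidentifiable")
  ratio <- ifelse(n_observable == 0, 0, n_observed / n_observable)
  10^ratio - 1
}

#' Read a peptide-identification table
#'
#' TSV with header `protein_id  peptide  n_parent_ions`: one row per observed
#' peptide with the number of distinct parent ions matched to it.
#'
#' @param path Path to the TSV file.
#' @return data.frame with those three columns.
#' @export
read_peptide_observations <- function(path) {
  obs <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "peptide", "n_parent_ions")
  if (!all(need %in% names(obs)))
    stop("peptide table must have columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(obs$peptide))) stop("empty peptide sequence in table")
  if (any(obs$n_parent_ions < 1)) stop("n_parent_ions must be positive")
  obs[need]
}

#' emPAI table for a proteome
#'
#' Computes, for every protein with at least one observed peptide,
#' N_observed (distinct observed peptide sequences by default, or total parent
#' ions in `"ions"` mode), N_observable from in-silico digestion and the scan
#' window, and the emPAI score. Peptides shared between proteins credit every
#' protein listing them.
#'
#' @param proteome A `proteome` object.
#' @param observations data.frame from [read_peptide_observations()].
#' @param dcfg,ocfg Digestion and observability configurations.
#' @param count_mode `"distinct"` (default) counts distinct peptide sequences;
#'   `"ions"` sums parent-ion counts.
#' @return data.frame `protein_id`, `n_observed`, `n_observable`, `empai`.
#' @export
empai_table <- function(proteome, observations,
                        dcfg = digestion_config(),
                        ocfg = observability_config(),
                        count_mode = c("distinct", "ions")) {
  count_mode <- match.arg(count_mode)
  rec <- proteome$records
  unknown <- setdiff(observations$protein_id, rec$protein_id)
  if (length(unknown))
    stop("observed protein(s) absent from proteome: ",
         paste(unknown, collapse = ", "))
  obs <- unique(observations[c("protein_id", "peptide", "n_parent_ions")])
  n_obs <- if (count_mode == "distinct") {
    tapply(obs$peptide, obs$protein_id, function(p) length(unique(p)))
  } else {
    tapply(obs$n_parent_ions, obs$protein_id, sum)
  }
  ids <- rec$protein_id[rec$protein_id %in% names(n_obs)]
  n_obsbl <- vapply(rec$sequence[match(ids, rec$protein_id)],
                    count_observable, integer(1),
                    dcfg = dcfg, ocfg = ocfg, USE.NAMES = FALSE)
  data.frame(protein_id = ids,
             n_observed = as.integer(n_obs[ids]),
             n_observable = n_obsbl,
             empai = empai_score(as.integer(n_obs[ids]), n_obsbl),
             stringsAsFactors = FALSE)
}

#' Molar fractions from emPAI scores
#'
#' Each protein's emPAI divided by the summed emPAI of the catalogue — its
#' estimated share of venom molecules ("fraction of venom").
#'
#' @param records data.frame with columns `protein_id` and `empai`.
#' @return The input with a `molar_fraction` column; fractions sum to 1.
#' @export
molar_fractions <- function(records) {
  total <- sum(records$empai)
  if (!length(records$empai) || total <= 0)
    stop("need at least one record with empai > 0")
  records$molar_fraction <- records$empai / total
  records
}
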