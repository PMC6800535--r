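# Shared fixtures and independent oracles for the test suite.

# Published constants used as test inputs (also shipped in extdata).
PUB_EXT <- extinction_set(eAb252 = 74311, eAb280 = 209409,
                          eD252 = 25600, eD280 = 4410)
TRAS_MW_FORMULA <- 145423
TRAS_MW_MEASURED <- 147836.9
PATH_CM <- 0.56

make_design <- function(linker = "SMCC", override = NULL,
                        drug_mw = 738.29) {
  conjugate_design(
    antibody_spec("trastuzumab", TRAS_MW_FORMULA, TRAS_MW_MEASURED),
    drug_spec("DM1", drug_mw),
    lookup_linker(linker),
    per_drug_mass_override_Da = override)
}

# Forward two-wavelength ratio map: the model dar_from_uv must invert.
forward_ratio <- function(dar, ext = PUB_EXT) {
  (ext$eAb252 + dar * ext$eD252) / (ext$eAb280 + dar * ext$eD280)
}

# Independent tryptic-digest oracle: residue-by-residue loop, deliberately
# a different algorithm from the vectorized implementation.
brute_digest <- function(seq_str, blocked = integer()) {
  ch <- strsplit(seq_str, "")[[1L]]
  peps <- character()
  cur <- ""
  for (i in seq_along(ch)) {
    cur <- paste0(cur, ch[i])
    cleave <- i < length(ch) &&
      (ch[i] == "R" || (ch[i] == "K" && !(i %in% blocked))) &&
      ch[i + 1L] != "P"
    if (cleave) { peps <- c(peps, cur); cur <- "" }
  }
  if (nzchar(cur)) peps <- c(peps, cur)
  peps
}

# Intervals (start, end) of a peptide list that tiles the parent.
peptide_intervals <- function(peps) {
  ends <- cumsum(nchar(peps))
  data.frame(start = c(1L, head(ends, -1L) + 1L), end = ends,
             sequence = peps)
}

random_protein <- function(n, k_frac = 0.1, r_frac = 0.08) {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  w <- rep((1 - k_frac - r_frac) / 18, 20)
  w[letters20 == "K"] <- k_frac
  w[letters20 == "R"] <- r_frac
  paste(sample(letters20, n, replace = TRUE, prob = w), collapse = "")
}

# Synthetic conjugate/reference spectrum pair with noise scaled to the
# noiseless apex (the "x% apex noise" convention).
gen_ms_pair <- function(mean_load, resolution = 300, noise_frac = 0,
                        seed = NULL, kind = "poisson", max_load = 8,
                        mz_step = 2) {
  design <- make_design("SMCC", override = 957.4)
  load_c <- load_distribution(kind, mean_load = mean_load,
                              max_load = max_load)
  load_r <- load_distribution("fixed", mean_load = 0, max_load = max_load)
  rng <- c(140000, 160000)
  one <- function(load, sub_seed) {
    quiet <- gen_maldi_spectrum(design, load,
                                instrument_model(resolution = resolution,
                                                 mz_step = mz_step),
                                mz_range = rng)
    if (noise_frac == 0) return(quiet)
    apex <- max(quiet$intensity)
    gen_maldi_spectrum(design, load,
                       instrument_model(resolution = resolution,
                                        noise_sd = noise_frac * apex,
                                        mz_step = mz_step),
                       mz_range = rng, seed = sub_seed)
  }
  list(conjugate = one(load_c, seed),
       reference = one(load_r, if (!is.null(seed)) seed + 1000L),
       design = design,
       true_mean = truncated_mean_load(load_c))
}
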