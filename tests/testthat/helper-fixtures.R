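# Shared fixtures and independent oracles; everything is generated in code.

# write a temporary NIfTI volume, return its path
write_tmp_nifti <- function(data, spacing = c(1, 1, 1)) {
  path <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  path
}

# independent Cohen's kappa for two raters (textbook formula)
cohen_kappa <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  po <- mean(a == b)
  pe <- sum(vapply(cats, function(c_) mean(a == c_) * mean(b == c_), 0))
  (po - pe) / (1 - pe)
}

# small default-condition nodule for pipeline tests (coarse grid for speed)
coarse_nodule <- function(noise_sd = 0, spacing = 0.15, seed = 1) {
  make_synthetic_nodule_volume(
    nodule_recipe(noise_sd = noise_sd, spacing = spacing,
                  margin = 0.6, seed = seed))
}

# responses from a single perfect reader over a small case set
perfect_responses <- function(n_cases = 6) {
  truth <- rep(c("printed", "patient"), length.out = n_cases)
  response_set(data.frame(
    reader_id = "R01", experience = "senior",
    case_id = sprintf("C%02d", seq_len(n_cases)),
    presentation = 1L, truth = truth, call = truth, confidence = 5L,
    stringsAsFactors = FALSE))
}

# Bernoulli reader responses with accuracy p (response-level independence)
bernoulli_responses <- function(n, p, seed) {
  set.seed(seed)
  truth <- sample(c("printed", "patient"), n, replace = TRUE)
  correct <- stats::runif(n) < p
  call <- ifelse(correct, truth,
                 ifelse(truth == "printed", "patient", "printed"))
  response_set(data.frame(
    reader_id = "R01", experience = "senior", case_id = "C01",
    presentation = 1L, truth = truth, call = call, confidence = 3L,
    stringsAsFactors = FALSE))
}

band_targets <- list(gg1 = c(-300, 0), gg2 = c(-500, -300),
                     gg3 = c(-750, -500))

# assemble the standard three-band phantom from a synthetic nodule
assemble_coarse_phantom <- function(syn) {
  lab <- threshold_classes(syn$volume)
  core <- class_mesh(lab, "core")
  bands <- lapply(names(band_targets), function(nm)
    list(mesh = class_mesh(lab, nm),
         spec = select_lattice(band_targets[[nm]])))
  names(bands) <- names(band_targets)
  assemble_partsolid_nodule(assembly_plan(core, bands))
}
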