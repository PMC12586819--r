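#' Recipe for a synthetic part-solid nodule volume
#'
#' Defines a concentric-sphere stand-in for a patient part-solid nodule:
#' a solid core above 0 HU surrounded by three ground-glass shells of
#' decreasing density, embedded in air, with optional Gaussian noise and
#' an optional lobulated surface perturbation for realism tests. The
#' default band means (+150, -150, -400, -625 HU) sit inside the
#' clinically observed ranges of solid cores and subsolid components and
#' inside their segmentation bands.
#'
#' @param core_radius solid-core radius in mm.
#' @param shell_outer_radii three strictly increasing outer radii (mm) of
#'   the gg1, gg2, gg3 shells; the first must exceed `core_radius`.
#' @param band_mean_hu named numeric (core, gg1, gg2, gg3) mean HU per
#'   band; must be ordered decreasing and lie inside the default class
#'   intervals.
#' @param noise_sd Gaussian noise SD in HU.
#' @param spacing isotropic voxel size in mm.
#' @param margin air margin around the outer shell in mm.
#' @param lobulation relative amplitude (0 = spheres) of a deterministic
#'   low-order angular perturbation of all radii.
#' @param seed RNG seed for the noise.
#' @return an object of class `nodule_recipe`.
#' @export
nodule_recipe <- function(core_radius = 2,
                          shell_outer_radii = c(3, 4, 5),
                          band_mean_hu = c(core = 150, gg1 = -150,
                                           gg2 = -400, gg3 = -625),
                          noise_sd = 30, spacing = 0.1, margin = 1,
                          lobulation = 0, seed = 1) {
  radii <- c(core_radius, shell_outer_radii)
  if (length(radii) != 4L || any(diff(radii) <= 0))
    stop("radii must be strictly increasing (core then three shells)",
         call. = FALSE)
  req <- c("core", "gg1", "gg2", "gg3")
  if (!all(req %in% names(band_mean_hu)))
    stop("band_mean_hu needs entries core, gg1, gg2, gg3", call. = FALSE)
  band_mean_hu <- band_mean_hu[req]
  if (any(diff(band_mean_hu) >= 0))
    stop("band means must be ordered core > gg1 > gg2 > gg3", call. = FALSE)
  classes <- default_hu_classes()
  for (i in 1:4) {
    if (!in_class(classes[[i]], band_mean_hu[i]))
      stop(sprintf("band mean %s = %g HU lies outside its class interval",
                   req[i], band_mean_hu[i]), call. = FALSE)
  }
  stopifnot(noise_sd >= 0, spacing > 0, margin >= 0, lobulation >= 0)
  structure(list(core_radius = core_radius,
                 shell_outer_radii = shell_outer_radii,
                 band_mean_hu = band_mean_hu, noise_sd = noise_sd,
                 spacing = spacing, margin = margin,
                 lobulation = lobulation, seed = seed),
            class = "nodule_recipe")
}

#' Generate a synthetic part-solid nodule HU volume
#'
#' Builds the concentric nodule of a [nodule_recipe()] on an isotropic
#' voxel grid, returning the volume together with ground truth for
#' recovery tests: per-band voxel counts/volumes and the generating band
#' of every voxel.
#'
#' @param recipe a [nodule_recipe()].
#' @return list with `volume` (an [hu_volume()]), `truth` (list:
#'   `band_voxels`, `band_volumes_mm3`, `analytic_volumes_mm3`,
#'   `band_labels` array with 0 = air, 1..4 = core, gg1, gg2, gg3), and
#'   the `recipe`.
#' @export
make_synthetic_nodule_volume <- function(recipe) {
  stopifnot(inherits(recipe, "nodule_recipe"))
  sp <- recipe$spacing
  r_out <- max(recipe$shell_outer_radii)
  half <- r_out + recipe$margin
  n <- as.integer(ceiling(2 * half / sp))
  ax <- (seq_len(n) - (n + 1) / 2) * sp
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  r <- sqrt(r2)
  if (recipe$lobulation > 0) {
    # deterministic low-order angular modulation of the radius field
    x <- array(rep(ax, times = n * n), dim = c(n, n, n))
    y <- aperm(x, c(2L, 1L, 3L))
    z <- aperm(x, c(3L, 2L, 1L))
    eps <- 1e-9
    mod <- 1 + recipe$lobulation *
      (x * y + 0.5 * y * z - 0.7 * x * z) / (r2 + eps)
    r <- r * mod
  }
  radii <- c(recipe$core_radius, recipe$shell_outer_radii)
  lab <- array(0L, dim = c(n, n, n))
  lab[r <= radii[4L]] <- 4L
  lab[r <= radii[3L]] <- 3L
  lab[r <= radii[2L]] <- 2L
  lab[r <= radii[1L]] <- 1L
  hu <- array(-1000, dim = c(n, n, n))
  for (b in 1:4) hu[lab == b] <- recipe$band_mean_hu[b]
  if (recipe$noise_sd > 0) {
    set.seed(recipe$seed)
    hu <- hu + stats::rnorm(length(hu), sd = recipe$noise_sd)
  }
  origin <- rep(ax[1L], 3L)  # grid centred on the nodule centre at 0
  vol <- hu_volume(hu, spacing = rep(sp, 3L), origin = origin, clamp = FALSE)
  voxvol <- sp^3
  band_voxels <- vapply(1:4, function(b) sum(lab == b), 0L)
  names(band_voxels) <- c("core", "gg1", "gg2", "gg3")
  sphere_vol <- 4 / 3 * pi * radii^3
  analytic <- c(sphere_vol[1L], diff(sphere_vol))
  names(analytic) <- names(band_voxels)
  list(volume = vol,
       truth = list(band_voxels = band_voxels,
                    band_volumes_mm3 = band_voxels * voxvol,
                    analytic_volumes_mm3 = analytic,
                    band_labels = lab),
       recipe = recipe)
}

#' Recipe for synthetic reader responses
#'
#' Emulates the blinded reading experiment: a panel of senior and
#' resident radiologists reads a set of nodule acquisitions (a subset of
#' which are 3D-printed), each presented several times, calling
#' printed/patient with group-specific sensitivity and specificity and
#' reporting Likert confidence. Defaults mirror the study conditions: 5
#' seniors + 12 residents, 21 acquisitions (14 printed, 7 patient), 3
#' presentations (1,071 responses), near-chance operating points, and a
#' confidence distribution peaked at the low-to-middle levels.
#'
#' @param n_senior,n_resident panel sizes.
#' @param n_cases number of unique acquisitions.
#' @param n_printed how many acquisitions are 3D-printed (the rest are
#'   patient nodules).
#' @param presentations presentations per acquisition.
#' @param sensitivity,specificity named numeric (`senior`, `resident`)
#'   per-group probabilities of a correct printed / patient call.
#' @param confidence_probs probabilities of Likert levels 1..5.
#' @param seed RNG seed.
#' @return an object of class `response_recipe`.
#' @export
response_recipe <- function(n_senior = 5, n_resident = 12, n_cases = 21,
                            n_printed = 14, presentations = 3,
                            sensitivity = c(senior = 0.424,
                                            resident = 0.568),
                            specificity = c(senior = 0.514,
                                            resident = 0.571),
                            confidence_probs = c(0.15, 0.30, 0.30,
                                                 0.17, 0.08),
                            seed = 1) {
  stopifnot(n_senior >= 0, n_resident >= 0, n_senior + n_resident >= 1,
            n_cases >= 1, n_printed >= 0, n_printed <= n_cases,
            presentations >= 1)
  probs <- c(sensitivity, specificity)
  if (any(probs < 0) || any(probs > 1))
    stop("sensitivity/specificity must lie in [0, 1]", call. = FALSE)
  if (length(confidence_probs) != 5L || any(confidence_probs < 0))
    stop("confidence_probs must be 5 non-negative weights", call. = FALSE)
  structure(list(n_senior = n_senior, n_resident = n_resident,
                 n_cases = n_cases, n_printed = n_printed,
                 presentations = presentations,
                 sensitivity = sensitivity, specificity = specificity,
                 confidence_probs = confidence_probs / sum(confidence_probs),
                 seed = seed),
            class = "response_recipe")
}

#' Generate synthetic reader responses
#'
#' @param recipe a [response_recipe()].
#' @return a [response_set()] with
#'   `n_readers * n_cases * presentations` rows; identical recipes
#'   (including seed) give identical response sets.
#' @export
make_synthetic_responses <- function(recipe) {
  stopifnot(inherits(recipe, "response_recipe"))
  set.seed(recipe$seed)
  readers <- data.frame(
    reader_id = sprintf("R%02d", seq_len(recipe$n_senior +
                                           recipe$n_resident)),
    experience = rep(c("senior", "resident"),
                     c(recipe$n_senior, recipe$n_resident)))
  truth_cases <- sample(rep(c("printed", "patient"),
                            c(recipe$n_printed,
                              recipe$n_cases - recipe$n_printed)))
  grid <- expand.grid(presentation = seq_len(recipe$presentations),
                      case = seq_len(recipe$n_cases),
                      reader = seq_len(nrow(readers)))
  truth <- truth_cases[grid$case]
  exp_ <- readers$experience[grid$reader]
  p_correct <- ifelse(truth == "printed",
                      recipe$sensitivity[exp_],
                      recipe$specificity[exp_])
  correct <- stats::runif(nrow(grid)) < p_correct
  call <- ifelse(correct, truth,
                 ifelse(truth == "printed", "patient", "printed"))
  conf <- sample(1:5, nrow(grid), replace = TRUE,
                 prob = recipe$confidence_probs)
  response_set(data.frame(
    reader_id = readers$reader_id[grid$reader],
    experience = exp_,
    case_id = sprintf("C%02d", grid$case),
    presentation = grid$presentation,
    truth = truth, call = call, confidence = conf,
    stringsAsFactors = FALSE))
}

#' Published reader-study contingency counts
#'
#' The overall, senior and resident confusion matrices of the blinded
#' reader study (17 radiologists x 21 acquisitions x 3 presentations =
#' 1,071 responses), as printed. Internal identities are asserted: senior
#' and resident counts add cellwise to the overall counts, with totals
#' 1,071 / 315 / 756.
#'
#' @return named list of [confusion_matrix()] objects: `overall`,
#'   `senior`, `resident`.
#' @export
printed_count_fixtures <- function() {
  overall <- confusion_matrix(tp = 375, fp = 159, fn = 339, tn = 198)
  senior <- confusion_matrix(tp = 89, fp = 51, fn = 121, tn = 54)
  resident <- confusion_matrix(tp = 286, fp = 108, fn = 218, tn = 144)
  for (cell in c("tp", "fp", "fn", "tn")) {
    stopifnot(overall[[cell]] == senior[[cell]] + resident[[cell]])
  }
  tot <- function(cm) cm$tp + cm$fp + cm$fn + cm$tn
  stopifnot(tot(overall) == 1071L, tot(senior) == 315L,
            tot(resident) == 756L)
  list(overall = overall, senior = senior, resident = resident)
}
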