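# Lazily computed, session-cached fixtures shared across test files.
# Expensive pipeline runs (template, registered cases, the QC suite) are
# computed once per test session.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, force(expr), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

fx_spec <- function() fx("spec", phantom_spec())

fx_template <- function() fx("template", make_template(fx_spec()))

# full-pipeline run at one severity (fixed seeds per severity level)
fx_severity_case <- function(s) {
  key <- paste0("sev_", s)
  fx(key, {
    tpl <- fx_template()
    subj <- subject_spec(severity = s, seed = 100L + round(100 * s))
    cs <- make_subject(tpl, subj, fx_spec())
    res <- run_case(cs$ct, tpl$template, tpl$atlas, tpl$brain,
                    pipeline_config(keep_intermediates = TRUE),
                    case_id = key)
    list(case = cs, result = res)
  })
}

# known rigid pose, no deformation: rotation 5 deg about z, (6, -4, 2) mm
fx_rigid_case <- function() {
  fx("rigid_case", {
    tpl <- fx_template()
    subj <- subject_spec(severity = 0, rotation_deg = c(0, 0, 5),
                         translation_mm = c(6, -4, 2),
                         deformation_amp = 0, noise_sd = 2, seed = 7L)
    cs <- make_subject(tpl, subj, fx_spec())
    pair <- register(cs$ct, tpl$template,
                     registration_settings(stages = c("rigid", "affine")))
    list(case = cs, subj = subj, pair = pair)
  })
}

# rigid + 3 mm sinusoidal deformation, full registration
fx_deform_case <- function() {
  fx("deform_case", {
    tpl <- fx_template()
    subj <- subject_spec(severity = 0, rotation_deg = c(2, -3, 5),
                         translation_mm = c(6, -4, 2),
                         deformation_amp = 3, noise_sd = 2, seed = 11L)
    cs <- make_subject(tpl, subj, fx_spec())
    pair <- register(cs$ct, tpl$template)
    warped <- resample(cs$ct, pair, image_grid(fx_spec()$dim,
                                               fx_spec()$spacing))
    list(case = cs, subj = subj, pair = pair, warped = warped)
  })
}

fx_qc_suite <- function() {
  fx("qc_suite", run_qc_suite(fx_template()))
}

# identity-pose subject (no transform), used by segmentation accuracy tests
fx_identity_case <- function() {
  fx("identity_case", {
    tpl <- fx_template()
    subj <- subject_spec(severity = 0, rotation_deg = c(0, 0, 0),
                         translation_mm = c(0, 0, 0),
                         deformation_amp = 0, noise_sd = 2, seed = 21L)
    make_subject(tpl, subj, fx_spec())
  })
}

# ground-truth world matrix of a rigid-only subject: native -> template
truth_world_matrix <- function(subj, spec) {
  R <- gwrct:::rotation_matrix(subj$rotation_deg)
  ctr <- gwrct:::phantom_center(spec)
  G <- diag(4)
  G[1:3, 1:3] <- R
  G[1:3, 4] <- ctr - R %*% ctr + subj$translation_mm
  G
}

# rotation angle (deg) and translation error (mm, at the head centre) of
# an estimated pull affine against the generator truth
rigid_error <- function(pair, subj, spec) {
  G <- truth_world_matrix(subj, spec)
  e <- pair$affine %*% G             # should be identity
  sv <- svd(e[1:3, 1:3])
  Rr <- sv$u %*% t(sv$v)             # polar rotation factor
  ang <- acos(min(1, max(-1, (sum(diag(Rr)) - 1) / 2))) * 180 / pi
  ctr <- gwrct:::phantom_center(spec)
  tc <- (e %*% c(ctr, 1))[1:3] - ctr
  c(rot_deg = ang, trans_mm = sqrt(sum(tc^2)))
}

# brute-force AUC over all positive-negative pairs (ties count one half)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

random_mask <- function(dim, p, seed) {
  set.seed(seed)
  binary_mask(array(runif(prod(dim)) < p, dim))
}
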