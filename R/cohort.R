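#' Functioning-item loading structure for a cohort dialect
#'
#' Returns the planted item-by-component loading matrix used by the
#' synthetic-cohort generator. Two instrument dialects are provided:
#' `"dataset1"` (11 clinician-rated items from the Birchwood Social
#' Functioning Scale and the Quality of Life scale) and `"dataset2"`
#' (8 items drawn from the Ham-D, MSIF, SAS and UPSA). Components are
#' ordered (independent, social, role) and every item is oriented so that a
#' higher value reflects better functioning.
#'
#' The loadings idealize the reported rotated pattern into identifiable
#' simple structure: items whose printed primary loading falls below 0.5 are
#' lifted to 0.5-0.55 and near-equal cross-loadings are dropped, so the
#' planted assignment of every item is recoverable at realistic sample
#' sizes; secondary loadings of at least 0.3 elsewhere are retained.
#'
#' @param dialect `"dataset1"` (default) or `"dataset2"`.
#' @return A numeric matrix, items x 3, with item rownames and component
#'   colnames.
#' @export
functioning_loadings <- function(dialect = c("dataset1", "dataset2")) {
  dialect <- match.arg(dialect)
  comp <- c("independent", "social", "role")
  if (dialect == "dataset1") {
    items <- c(
      "BSFS Social Engagement Withdrawal",
      "BSFS Interpersonal Communication",
      "BSFS Prosocial Activities",
      "BSFS Recreation",
      "BSFS Independence Performance",
      "BSFS Independence Competence",
      "BSFS Occupation Employment",
      "QoL Interpersonal Relationships",
      "QoL Instrumental Role",
      "QoL Intrapsychic Foundations",
      "QoL Common Objects Activities"
    )
    L <- matrix(0, length(items), 3, dimnames = list(items, comp))
    L["BSFS Social Engagement Withdrawal", "social"] <- 0.63
    L["BSFS Interpersonal Communication", "social"] <- 0.89
    L["BSFS Prosocial Activities", c("independent", "social")] <- c(0.62, 0.40)
    L["BSFS Recreation", "independent"] <- 0.91
    L["BSFS Independence Performance", "independent"] <- 0.76
    L["BSFS Independence Competence", "independent"] <- 0.50
    L["BSFS Occupation Employment", "role"] <- 0.93
    L["QoL Interpersonal Relationships", "social"] <- 0.69
    L["QoL Instrumental Role", c("independent", "role")] <- c(0.31, 0.88)
    L["QoL Intrapsychic Foundations", "independent"] <- 0.55
    L["QoL Common Objects Activities", "independent"] <- 0.60
  } else {
    items <- c(
      "UPSA Financial Skills",
      "UPSA Communication Skills",
      "MSIF Global Residential Functioning",
      "SAS Degree of Social Activity",
      "SAS Social Frequency",
      "HamD Work and Interests",
      "SAS Leisure Activities",
      "MSIF Global Role Functioning"
    )
    L <- matrix(0, length(items), 3, dimnames = list(items, comp))
    L["UPSA Financial Skills", "independent"] <- 0.85
    L["UPSA Communication Skills", "independent"] <- 0.84
    L["MSIF Global Residential Functioning", "independent"] <- 0.59
    L["SAS Degree of Social Activity", "social"] <- 0.91
    L["SAS Social Frequency", "social"] <- 0.87
    L["HamD Work and Interests", "role"] <- 0.87
    L["SAS Leisure Activities", "social"] <- 0.47
    L["MSIF Global Role Functioning", c("independent", "role")] <- c(0.32, 0.55)
  }
  L
}

#' The 65 biopsychosocial predictors
#'
#' The predictor battery used for phenotype classification: sociodemographic
#' and personal characteristics (DEMO), clinical symptom ratings (SYMP),
#' general neurocognition (COG), social cognition (SCOG), subjective
#' psychological experiences (SELF), and structural brain volumes (MRI),
#' with bilateral volumes carried as separate left/right predictors.
#'
#' @return A tibble with columns `name`, `block`, `kind` (`"continuous"` or
#'   `"binary"`), and `bilateral_pair` (shared id for left/right volume
#'   pairs, `NA` otherwise).
#' @export
predictor_table <- function() {
  demo <- c("Sex", "Age", "Ethnicity Hispanic", "Race White", "Race Black",
            "Race Asian", "English Primary Language", "Family Hx SSD",
            "Parental Educational Attainment", "Age of Onset",
            "Duration of Illness")
  demo_kind <- c("binary", "continuous", "binary", "binary", "binary",
                 "binary", "binary", "binary", "continuous", "continuous",
                 "continuous")
  symp <- c("BPRS Anxiety and Depression", "BPRS Positive Symptoms",
            "BPRS Activation", "BPRS Hostility", "SANS Affective Flattening",
            "SANS Alogia", "SANS Avolition", "SANS Anhedonia")
  cog <- c("Processing Speed", "Attention and Vigilance", "Working Memory",
           "Verbal Learning", "Visual Learning",
           "Reasoning and Problem Solving", "WTAR Standard Score")
  scog <- c("MSCEIT", "ER40 Accuracy", "ER40 Speed", "TASIT Total Score",
            "RMET Total Score", "RAD Total Score")
  self <- c("IRI Perspective Taking", "IRI Fantasy", "IRI Empathic Concern",
            "IRI Personal Distress", "SPQ Cognitive and Perceptual",
            "SPQ Interpersonal", "SPQ Disorganized")
  regions <- c("Superior Temporal", "Entorhinal", "Hippocampal", "Amygdala",
               "Thalamic", "Superior Frontal", "Caudal Middle Frontal",
               "Lateral Orbitofrontal", "Medial Orbitofrontal",
               "Rostral Middle Frontal", "Inferior Frontal")
  mri <- c("Total Ventricular Volume", "Total Brain Volume",
           "Total Gray Matter Volume",
           as.vector(t(outer(regions, c("Left", "Right"),
                             function(r, s) paste(s, r, "Volume")))),
           "Mean Prefrontal Cortical Volume")
  tbl <- tibble::tibble(
    name = c(demo, symp, cog, scog, self, mri),
    block = c(rep("DEMO", length(demo)), rep("SYMP", length(symp)),
              rep("COG", length(cog)), rep("SCOG", length(scog)),
              rep("SELF", length(self)), rep("MRI", length(mri))),
    kind = c(demo_kind, rep("continuous",
                            length(symp) + length(cog) + length(scog) +
                              length(self) + length(mri)))
  )
  tbl$bilateral_pair <- NA_character_
  for (r in regions) {
    idx <- tbl$name %in% paste(c("Left", "Right"), r, "Volume")
    tbl$bilateral_pair[idx] <- r
  }
  tbl
}

#' Default within-cluster component covariance
#'
#' Covariance of the latent functioning components around a participant's
#' cluster profile. The default is structured rather than isotropic: role
#' functioning disperses widely within phenotype (employment status is
#' volatile even among otherwise similar patients), and independent vs
#' social engagement trade off (negative correlation), while overall level
#' varies little within a phenotype. These are directions along which the
#' three cluster profiles barely differ, so each functioning domain
#' carries its own common variance — making the planted three-component
#' structure recoverable — without blurring the cluster separation.
#'
#' @return A 3 x 3 covariance matrix (independent, social, role).
#' @export
default_component_noise <- function() {
  u <- c(1, -1, 0) / sqrt(2)          # independent-vs-social trade-off
  e3 <- c(0, 0, 1)                    # role-specific dispersion
  m <- 0.9^2 * tcrossprod(u) + 1.8^2 * tcrossprod(e3) + 0.45^2 * diag(3)
  dimnames(m) <- list(c("independent", "social", "role"),
                      c("independent", "social", "role"))
  m
}

#' Default planted predictor effects
#'
#' Cluster means (in SD units) for the informative predictors of the default
#' synthetic cohort, chosen to emulate the dissociation seen in the study
#' population: avolition severe in clusters 1 and 2 but not 3 (tracking role
#' functioning), anhedonia severe only in cluster 1 (tracking independent
#' and social functioning), emotional intelligence (MSCEIT) elevated in
#' cluster 3, and graded neurocognition.
#'
#' @return A named list of length-3 numeric vectors (cluster means).
#' @export
default_predictor_effects <- function() {
  list(
    "SANS Avolition"           = c(0.7, 0.7, -1.1),
    "SANS Anhedonia"           = c(1.2, -0.4, -0.4),
    "MSCEIT"                   = c(-0.5, -0.5, 0.8),
    "Processing Speed"         = c(-0.6, 0.0, 0.6),
    "Visual Learning"          = c(-0.4, 0.0, 0.4),
    "SANS Affective Flattening" = c(0.5, 0.1, -0.4),
    "BPRS Positive Symptoms"   = c(0.4, 0.1, -0.35)
  )
}

#' Default interaction-only predictor effects
#'
#' Predictors whose cluster separation is conditional on another predictor's
#' tertile (sign +1 in the partner's top tertile, -1 in the bottom, 0 in the
#' middle), so they carry classification signal without large marginal group
#' differences — the behaviour expected of left hippocampal volume and the
#' IRI Fantasy / Personal Distress subscales.
#'
#' @return A named list; each element is `list(partner = <name>,
#'   means = <length-3 numeric>)`.
#' @export
default_interaction_effects <- function() {
  list(
    "Left Hippocampal Volume" =
      list(partner = "SANS Avolition", means = c(-0.8, 0.0, 0.8)),
    "IRI Fantasy" =
      list(partner = "SANS Anhedonia", means = c(-0.7, 0.7, 0.0)),
    "IRI Personal Distress" =
      list(partner = "MSCEIT", means = c(0.7, 0.0, -0.7))
  )
}

#' Configuration for a synthetic cohort
#'
#' Bundles every knob of the generator. Defaults reproduce the Dataset-I
#' study conditions: n = 282 participants, three latent phenotype clusters
#' with prevalences 25/36/39%, the 11-item functioning battery loading on
#' three correlated components, 65 biopsychosocial predictors with planted
#' marginal and interaction-only effects, bilateral brain volumes correlated
#' at r = 0.84, and 2% MCAR missingness in the predictors.
#'
#' @param n_participants Cohort size.
#' @param prevalences Length-3 cluster proportions summing to 1.
#' @param component_profiles 3 x 3 matrix of latent component means
#'   (clusters x (independent, social, role)), in SD units.
#' @param item_loadings Items x 3 loading matrix (see
#'   [functioning_loadings()]).
#' @param item_noise_sd Unique-noise SD added to each functioning item.
#' @param component_noise Within-cluster variation of the latent component
#'   scores: a single SD (isotropic), a length-3 SD vector, or a full
#'   3 x 3 covariance matrix (default [default_component_noise()]). Without
#'   within-cluster component variation the three cluster mean vectors span
#'   only two dimensions and the planted 3-component structure would be
#'   rank deficient.
#' @param predictors Predictor definition tibble as from [predictor_table()]
#'   (columns `name`, `kind`, optional `block`, `bilateral_pair`).
#' @param predictor_effects Named list of length-3 cluster means for
#'   informative predictors.
#' @param interaction_effects Named list of interaction-only effects (see
#'   [default_interaction_effects()]).
#' @param bilateral_r Correlation of the paired left/right volume noise.
#' @param missing_rate MCAR missingness probability per predictor cell,
#'   in \[0, 1).
#' @param seed Integer seed; the only source of randomness.
#' @param dialect Functioning-instrument dialect used when `item_loadings`
#'   is not supplied.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 282,
                          prevalences = c(0.25, 0.36, 0.39),
                          component_profiles = NULL,
                          item_loadings = NULL,
                          item_noise_sd = 0.35,
                          component_noise = default_component_noise(),
                          predictors = predictor_table(),
                          predictor_effects = default_predictor_effects(),
                          interaction_effects = default_interaction_effects(),
                          bilateral_r = 0.84,
                          missing_rate = 0.02,
                          seed = 1L,
                          dialect = c("dataset1", "dataset2")) {
  dialect <- match.arg(dialect)
  if (!is.numeric(n_participants) || n_participants < 1) {
    abort("`n_participants` must be a positive integer")
  }
  if (length(prevalences) != 3L || any(prevalences < 0) ||
      abs(sum(prevalences) - 1) > 1e-12) {
    abort("`prevalences` must be 3 non-negative proportions summing to 1")
  }
  if (is.null(item_loadings)) item_loadings <- functioning_loadings(dialect)
  if (any(apply(abs(item_loadings), 1, max) < 0.3)) {
    abort("every row of `item_loadings` needs at least one loading >= 0.3")
  }
  if (is.null(component_profiles)) {
    component_profiles <- rbind(
      c(-1.6, -1.6, -1.3),  # cluster 1: impaired across domains
      c( 0.0,  0.9, -1.3),  # cluster 2: role impaired, social near-preserved
      c( 1.9,  1.9,  2.1)   # cluster 3: resilient
    )
    colnames(component_profiles) <- c("independent", "social", "role")
  }
  if (is.matrix(component_noise)) {
    stopifnot(all(dim(component_noise) == ncol(item_loadings)))
  } else {
    component_noise <- diag(rep_len(component_noise^2,
                                    ncol(item_loadings)),
                            ncol(item_loadings))
  }
  stopifnot(is.matrix(component_profiles),
            all(dim(component_profiles) == c(3L, ncol(item_loadings))))
  if (abs(bilateral_r) > 1) abort("`bilateral_r` must lie in [-1, 1]")
  check_scalar_prop(missing_rate, "missing_rate", 0, 1, open_hi = TRUE)
  bad <- setdiff(c(names(predictor_effects),
                   names(interaction_effects),
                   vapply(interaction_effects, `[[`, "", "partner")),
                 predictors$name)
  if (length(bad)) {
    abort(paste0("unknown predictor names in effects map: ",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(n_participants = as.integer(n_participants),
         prevalences = prevalences,
         component_profiles = component_profiles,
         item_loadings = item_loadings,
         item_noise_sd = item_noise_sd,
         component_noise = component_noise,
         predictors = predictors,
         predictor_effects = predictor_effects,
         interaction_effects = interaction_effects,
         bilateral_r = bilateral_r,
         missing_rate = missing_rate,
         seed = as.integer(seed),
         dialect = dialect),
    class = "cohort_config")
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws cluster labels from the configured prevalences, latent component
#' scores around each cluster's profile, functioning items as noisy linear
#' combinations of the components, and predictors as standard-normal noise
#' plus the configured cluster effects; designated left/right volume pairs
#' share correlated noise, interaction-only predictors gain cluster
#' separation whose sign depends on the partner predictor's tertile, and
#' MCAR missingness is injected at the configured rate. Fully reproducible
#' from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `fp_cohort`: a list with tibbles
#'   `participants` (id, true cluster), `functioning`, `predictors`
#'   (missing cells as `NA`), the `predictor_info` table and the config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  L <- config$item_loadings
  ptab <- config$predictors
  p <- nrow(ptab)

  cohort <- with_seed(config$seed, {
    labels <- sample.int(3L, n, replace = TRUE, prob = config$prevalences)
    latent <- config$component_profiles[labels, , drop = FALSE] +
      matrix(rnorm(n * ncol(L)), n) %*% chol(config$component_noise)
    functioning <- latent %*% t(L) +
      matrix(rnorm(n * nrow(L), sd = config$item_noise_sd), n)
    colnames(functioning) <- rownames(L)

    X <- matrix(NA_real_, n, p, dimnames = list(NULL, ptab$name))
    pair_id <- if ("bilateral_pair" %in% names(ptab)) ptab$bilateral_pair
               else rep(NA_character_, p)
    r <- config$bilateral_r
    for (j in seq_len(p)) {
      if (!is.na(X[1L, j])) next  # right member already drawn with its left
      if (ptab$kind[j] == "binary") {
        X[, j] <- as.double(runif(n) < binary_prevalence(ptab$name[j]))
      } else if (!is.na(pair_id[j])) {
        partner <- which(pair_id == pair_id[j])
        partner <- setdiff(partner, j)
        z1 <- rnorm(n)
        X[, j] <- z1
        if (length(partner) == 1L) {
          X[, partner] <- r * z1 + sqrt(1 - r^2) * rnorm(n)
        }
      } else {
        X[, j] <- rnorm(n)
      }
    }
    for (nm in names(config$predictor_effects)) {
      X[, nm] <- X[, nm] + config$predictor_effects[[nm]][labels]
    }
    for (nm in names(config$interaction_effects)) {
      eff <- config$interaction_effects[[nm]]
      part <- X[, eff$partner]
      qs <- quantile(part, c(1 / 3, 2 / 3), names = FALSE)
      sgn <- ifelse(part > qs[2L], 1, ifelse(part < qs[1L], -1, 0))
      X[, nm] <- X[, nm] + eff$means[labels] * sgn
    }

    ids <- sprintf("P%0*d", max(3L, nchar(n)), seq_len(n))
    structure(
      list(participants = tibble::tibble(participant_id = ids,
                                         true_cluster = labels),
           functioning = dplyr::bind_cols(
             tibble::tibble(participant_id = ids),
             tibble::as_tibble(functioning)),
           predictors = dplyr::bind_cols(
             tibble::tibble(participant_id = ids),
             tibble::as_tibble(X)),
           predictor_info = ptab,
           missing_info = list(rate = 0, n_masked = 0L),
           config = config),
      class = "fp_cohort")
  })
  if (config$missing_rate > 0) {
    cohort <- inject_missingness(cohort, config$missing_rate,
                                 seed = stage_seed(config$seed, "missingness"))
  }
  cohort
}

# Population prevalences for the binary demographic indicators, matched to
# the Dataset-I sample description.
binary_prevalence <- function(name) {
  switch(name,
         "Sex" = 0.344,
         "Ethnicity Hispanic" = 0.12,
         "Race White" = 0.51,
         "Race Black" = 0.34,
         "Race Asian" = 0.15,
         "English Primary Language" = 0.80,
         "Family Hx SSD" = 0.20,
         0.5)
}

#' Inject MCAR missingness into a cohort's predictors
#'
#' Each predictor cell is independently set missing with probability `rate`;
#' functioning items are never masked.
#'
#' @param cohort An `fp_cohort`.
#' @param rate Missingness probability in \[0, 1).
#' @param seed Integer seed for the mask draw.
#' @return The cohort with masked predictor cells set to `NA`;
#'   `cohort$missing_info` records the rate, seed and number of newly
#'   masked cells.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  stopifnot(inherits(cohort, "fp_cohort"))
  check_scalar_prop(rate, "rate", 0, 1, open_hi = TRUE)
  X <- as.matrix(cohort$predictors[, -1L])
  mask <- with_seed(seed, matrix(runif(length(X)) < rate,
                                 nrow(X), ncol(X)))
  n_new <- sum(mask & !is.na(X))
  X[mask] <- NA_real_
  cohort$predictors[, -1L] <- tibble::as_tibble(X)
  cohort$missing_info <- list(rate = rate, n_masked = n_new, seed = seed)
  cohort
}

#' Missingness mask of a cohort
#'
#' @param cohort An `fp_cohort`.
#' @return Logical matrix (participants x predictors), `TRUE` where missing.
#' @export
cohort_missing_mask <- function(cohort) {
  stopifnot(inherits(cohort, "fp_cohort"))
  m <- is.na(as.matrix(cohort$predictors[, -1L]))
  rownames(m) <- cohort$predictors$participant_id
  m
}

#' @export
print.fp_cohort <- function(x, ...) {
  cat(sprintf(
    "<fp_cohort> %d participants, %d functioning items, %d predictors\n",
    nrow(x$participants), ncol(x$functioning) - 1L,
    ncol(x$predictors) - 1L))
  shares <- table(factor(x$participants$true_cluster, 1:3)) /
    nrow(x$participants)
  cat(sprintf("  true cluster shares: %s\n",
              paste(sprintf("%.1f%%", 100 * shares), collapse = " / ")))
  cat(sprintf("  missing predictor cells: %d\n",
              sum(is.na(as.matrix(x$predictors[, -1L])))))
  invisible(x)
}

#' Write a cohort to a directory of CSV files
#'
#' Writes `participants.csv` (id, true cluster), `functioning.csv` and
#' `predictors.csv` (missing cells as empty fields), UTF-8 with a header
#' row and `.` decimal.
#'
#' @param cohort An `fp_cohort`.
#' @param directory Target directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "fp_cohort"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  utils::write.csv(cohort$participants,
                   file.path(directory, "participants.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$functioning,
                   file.path(directory, "functioning.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$predictors,
                   file.path(directory, "predictors.csv"),
                   row.names = FALSE, na = "")
  invisible(directory)
}

read_numeric_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"participant_id" %in% names(raw)) {
    abort(sprintf("malformed header in %s: no participant_id column",
                  basename(path)))
  }
  if (anyDuplicated(raw$participant_id)) {
    abort(sprintf("duplicate participant IDs in %s", basename(path)))
  }
  out <- raw
  for (j in setdiff(names(raw), "participant_id")) {
    v <- raw[[j]]
    empty <- v == ""
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !empty)) {
      abort(sprintf("non-numeric cell in column '%s' of %s", j,
                    basename(path)))
    }
    num[empty] <- NA_real_
    out[[j]] <- num
  }
  tibble::as_tibble(out)
}

#' Read a cohort written by [write_cohort()]
#'
#' Empty predictor fields are read back as missing (`NA`), never as zero.
#'
#' @param directory Directory containing the three cohort CSVs.
#' @return An `fp_cohort` (with `predictor_info` reconstructed from the
#'   default predictor table where the names match, otherwise minimal).
#' @export
read_cohort <- function(directory) {
  participants <- read_numeric_csv(file.path(directory, "participants.csv"))
  participants$true_cluster <- as.integer(participants$true_cluster)
  functioning <- read_numeric_csv(file.path(directory, "functioning.csv"))
  if (anyNA(as.matrix(functioning[, -1L]))) {
    abort("functioning table must not contain missing cells")
  }
  predictors <- read_numeric_csv(file.path(directory, "predictors.csv"))
  nm <- setdiff(names(predictors), "participant_id")
  full <- predictor_table()
  info <- if (all(nm %in% full$name)) {
    full[match(nm, full$name), ]
  } else {
    tibble::tibble(name = nm, block = "CUSTOM", kind = "continuous",
                   bilateral_pair = NA_character_)
  }
  structure(
    list(participants = participants, functioning = functioning,
         predictors = predictors, predictor_info = info,
         missing_info = list(rate = NA_real_,
                             n_masked = sum(is.na(as.matrix(
                               predictors[, -1L])))),
         config = NULL),
    class = "fp_cohort")
}
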