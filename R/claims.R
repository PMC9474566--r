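#' Generator configuration for synthetic claims
#'
#' Bundles the parameters of the synthetic outpatient-claims generator. The
#' defaults describe the study population the package is designed around: a
#' regional network of 113 office-based physicians treating children and
#' adolescents, with roughly one in five physicians providing primary care
#' (general practitioners, including pediatricians), each patient anchored
#' at a home GP, specialist consultations that are referral-mediated in a
#' minority of encounters, and occasional self-directed second opinions at
#' another GP.
#'
#' @param n_physicians number of physicians (at least 3; triadic model terms
#'   are undefined below that).
#' @param gp_fraction proportion of physicians coded as GPs; the roster gets
#'   exactly `round(gp_fraction * n_physicians)` GPs.
#' @param n_patients number of patients.
#' @param distance_decay softmax inverse temperature (per minute of travel
#'   time) governing how strongly patients and referral targets favour
#'   nearby physicians; larger values concentrate choice on close providers.
#' @param mean_specialist_visits Poisson mean of the number of specialist
#'   encounters per patient.
#' @param p_referral probability that a specialist encounter is
#'   referral-mediated (referrer = the patient's home GP).
#' @param p_second_opinion probability that a patient adds one self-directed
#'   encounter at a GP other than the home GP.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return an object of class `generator_config`.
#' @seealso [generate_roster()], [generate_claims()]
#' @export
#' @examples
#' cfg <- generator_config(n_physicians = 20, n_patients = 100, seed = 7)
#' ros <- generate_roster(cfg)
#' cl  <- generate_claims(ros$roster, ros$travel_time, cfg)
#' head(cl)
generator_config <- function(n_physicians = 113,
                             gp_fraction = 0.2,
                             n_patients = 3000,
                             distance_decay = 0.4,
                             mean_specialist_visits = 2.5,
                             p_referral = 0.12,
                             p_second_opinion = 0.15,
                             seed = 1L) {
  cfg <- list(
    n_physicians = as.integer(n_physicians),
    gp_fraction = gp_fraction,
    n_patients = as.integer(n_patients),
    distance_decay = distance_decay,
    mean_specialist_visits = mean_specialist_visits,
    p_referral = p_referral,
    p_second_opinion = p_second_opinion,
    seed = as.integer(seed)
  )
  for (p in c("gp_fraction", "p_referral", "p_second_opinion")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$n_physicians < 3L) {
    stop("n_physicians must be at least 3 (triadic terms are undefined otherwise)")
  }
  if (cfg$n_patients < 1L) stop("n_patients must be positive")
  if (cfg$distance_decay <= 0) stop("distance_decay must be positive")
  if (cfg$mean_specialist_visits < 0) stop("mean_specialist_visits must be nonnegative")
  class(cfg) <- "generator_config"
  cfg
}

GP_SPECIALTIES <- c("general_practice", "pediatrics")
SPECIALIST_SPECIALTIES <- c("dermatology", "ophthalmology", "ent",
                            "orthopedics", "cardiology", "neurology",
                            "surgery", "radiology")

#' Generate a synthetic physician roster and travel-time matrix
#'
#' Physicians are placed i.i.d. uniformly on a square of side
#' `r REGION_KM` km; pairwise travel time is Euclidean distance times a
#' fixed factor of `r MINUTES_PER_KM` minutes per km. Roles are assigned to
#' a random subset of `round(gp_fraction * n)` physicians; status, practice
#' form and specialty are drawn from fixed categorical distributions
#' (GPs from general practice/pediatrics, specialists from eight
#' disciplines).
#'
#' @param config a [generator_config()].
#' @return a list with components `roster` (a `physician_roster`) and
#'   `travel_time` (a `travel_time_matrix`), both in the same physician
#'   order. Deterministic given `config$seed`.
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_physicians
  ids <- sprintf("phys_%03d", seq_len(n))
  n_gp <- as.integer(round(config$gp_fraction * n))
  role <- integer(n)
  role[sample.int(n, n_gp)] <- 1L

  status <- sample(ROSTER_STATUS_LEVELS, n, replace = TRUE,
                   prob = c(0.70, 0.20, 0.10))
  practice <- sample(ROSTER_PRACTICE_LEVELS, n, replace = TRUE,
                     prob = c(0.55, 0.35, 0.10))
  specialty <- character(n)
  specialty[role == 1L] <- sample(GP_SPECIALTIES, sum(role), replace = TRUE)
  specialty[role == 0L] <- sample(SPECIALIST_SPECIALTIES, n - sum(role),
                                  replace = TRUE)
  x <- runif(n, 0, REGION_KM)
  y <- runif(n, 0, REGION_KM)

  roster <- as_physician_roster(data.frame(
    physician_id = ids, role = role, status = status,
    practice_form = practice, specialty = specialty,
    x_km = x, y_km = y, stringsAsFactors = FALSE))

  d <- as.matrix(stats::dist(cbind(x, y))) * MINUTES_PER_KM
  dimnames(d) <- list(ids, ids)
  list(roster = roster, travel_time = as_travel_time_matrix(d))
}

#' Generate a synthetic claims table
#'
#' Emulates outpatient care pathways for a pediatric patient population.
#' Each patient, located uniformly in the study region, (a) picks a home GP
#' with probability proportional to `exp(-distance_decay * travel_time)` and
#' records a non-referral encounter there; (b) makes
#' `k ~ Poisson(mean_specialist_visits)` specialist visits, each chosen with
#' the same softmax rule on the travel time from the home GP, and each
#' flagged as a referral (referrer = home GP) independently with probability
#' `p_referral`; and (c) with probability `p_second_opinion` adds one
#' self-directed encounter at another GP near the home GP. Random draws are
#' staged so that changing `p_referral` alone only re-thresholds the same
#' uniforms: the set of referral-flagged rows grows monotonically in
#' `p_referral` under a fixed seed.
#'
#' Ground truth for validation is attached to the result: a column
#' `encounter_type` (`home_gp`, `specialist_referral`, `specialist_direct`,
#' `second_opinion`) and an attribute `home_gp` (named character vector
#' mapping patient id to home-GP id). [write_claims()] drops both.
#'
#' @param roster a `physician_roster` with at least one GP and one
#'   specialist.
#' @param ttm the matching `travel_time_matrix`.
#' @param config a [generator_config()]; claims use seed `config$seed + 1`
#'   so that roster and claims draw from distinct streams.
#' @return a `claims_table`: data frame with columns `patient_id`,
#'   `physician_id`, `referral_flag` (logical), `referring_physician_id`
#'   (NA when not referral) and `encounter_type`, deduplicated on the first
#'   four columns.
#' @export
generate_claims <- function(roster, ttm, config) {
  stopifnot(inherits(config, "generator_config"))
  validate_roster(roster)
  validate_ttm(ttm)
  if (!identical(rownames(ttm), roster$physician_id)) {
    stop("travel-time matrix must be indexed like the roster")
  }
  gp_idx <- which(roster$role == 1L)
  sp_idx <- which(roster$role == 0L)
  if (length(gp_idx) < 1L || length(sp_idx) < 1L) {
    stop("roster must contain at least one GP and one specialist")
  }
  set.seed(config$seed + 1L)
  np <- config$n_patients
  ids <- roster$physician_id
  decay <- config$distance_decay

  # Stage 1: patient locations on the roster's bounding box.
  px <- runif(np, min(roster$x_km), max(roster$x_km))
  py <- runif(np, min(roster$y_km), max(roster$y_km))

  # Stage 2: home GP via softmax over patient-to-GP travel time.
  tt_pg <- outer(px, roster$x_km[gp_idx], "-")^2 +
           outer(py, roster$y_km[gp_idx], "-")^2
  tt_pg <- sqrt(tt_pg) * MINUTES_PER_KM
  w <- exp(-decay * tt_pg)
  home_gp <- vapply(seq_len(np), function(i) {
    gp_idx[sample.int(length(gp_idx), 1L, prob = w[i, ])]
  }, integer(1))

  # Stage 3: number of specialist visits per patient.
  k <- rpois(np, config$mean_specialist_visits)

  # Stage 4: specialist choices, softmax on travel time from the home GP.
  # Drawn grouped by home GP so the draw order does not depend on
  # p_referral or p_second_opinion.
  sp_patient <- rep.int(seq_len(np), k)
  sp_choice <- integer(length(sp_patient))
  for (g in sort(unique(home_gp))) {
    sel <- which(home_gp[sp_patient] == g)
    if (length(sel) == 0L) next
    wg <- exp(-decay * ttm[g, sp_idx])
    sp_choice[sel] <- sp_idx[sample.int(length(sp_idx), length(sel),
                                        replace = TRUE, prob = wg)]
  }

  # Stage 5: referral flags from a dedicated uniform stream.
  ref_flag <- runif(length(sp_patient)) < config$p_referral

  # Stage 6: self-directed second opinions at another GP.
  second <- runif(np) < config$p_second_opinion
  if (length(gp_idx) < 2L) second[] <- FALSE  # no alternative GP exists
  second_gp <- integer(np)
  for (i in which(second)) {
    alt <- setdiff(gp_idx, home_gp[i])
    wg <- exp(-decay * ttm[home_gp[i], alt])
    second_gp[i] <- if (length(alt) == 1L) alt else
      alt[sample.int(length(alt), 1L, prob = wg)]
  }

  pat_id <- function(i) sprintf("pat_%05d", i)
  claims <- rbind(
    data.frame(patient_id = pat_id(seq_len(np)),
               physician_id = ids[home_gp],
               referral_flag = FALSE,
               referring_physician_id = NA_character_,
               encounter_type = "home_gp",
               stringsAsFactors = FALSE),
    data.frame(patient_id = pat_id(sp_patient),
               physician_id = ids[sp_choice],
               referral_flag = ref_flag,
               referring_physician_id = ifelse(ref_flag,
                                               ids[home_gp[sp_patient]],
                                               NA_character_),
               encounter_type = ifelse(ref_flag, "specialist_referral",
                                       "specialist_direct"),
               stringsAsFactors = FALSE),
    if (any(second)) data.frame(
      patient_id = pat_id(which(second)),
      physician_id = ids[second_gp[second]],
      referral_flag = FALSE,
      referring_physician_id = NA_character_,
      encounter_type = "second_opinion",
      stringsAsFactors = FALSE)
  )
  claims <- claims[order(claims$patient_id, claims$physician_id), ]
  rownames(claims) <- NULL
  claims <- as_claims_table(claims, roster = roster)
  attr(claims, "home_gp") <- stats::setNames(ids[home_gp], pat_id(seq_len(np)))
  claims
}

#' Claims tables
#'
#' A claims table holds encounter-level records: columns `patient_id`,
#' `physician_id`, `referral_flag` (logical) and `referring_physician_id`
#' (NA unless the encounter was referral-mediated). Rows are deduplicated on
#' those four columns. Referral rows must name a referrer different from the
#' treating physician, and all physician ids must appear in the roster when
#' one is supplied.
#'
#' @param claims data frame with at least the four columns above.
#' @param roster optional `physician_roster` to validate ids against.
#' @return a validated `claims_table`.
#' @export
as_claims_table <- function(claims, roster = NULL) {
  claims <- as.data.frame(claims, stringsAsFactors = FALSE)
  required <- c("patient_id", "physician_id", "referral_flag",
                "referring_physician_id")
  missing <- setdiff(required, names(claims))
  if (length(missing) > 0L) {
    stop("claims table is missing column(s): ", paste(missing, collapse = ", "))
  }
  claims$referral_flag <- as.logical(claims$referral_flag)
  bad <- claims$referral_flag &
    (is.na(claims$referring_physician_id) |
     claims$referring_physician_id == claims$physician_id)
  if (any(bad)) {
    stop("referral rows must carry a referring_physician_id distinct from ",
         "physician_id (", sum(bad), " offending row(s))")
  }
  if (any(!claims$referral_flag & !is.na(claims$referring_physician_id))) {
    stop("non-referral rows must not carry a referring_physician_id")
  }
  if (!is.null(roster)) {
    known <- roster$physician_id
    unknown <- setdiff(c(claims$physician_id,
                         claims$referring_physician_id[!is.na(claims$referring_physician_id)]),
                       known)
    if (length(unknown) > 0L) {
      stop("claims reference physician id(s) absent from the roster: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  key <- claims[, required]
  claims <- claims[!duplicated(key), , drop = FALSE]
  rownames(claims) <- NULL
  class(claims) <- c("claims_table", "data.frame")
  claims
}

#' Read and write claims tables
#'
#' CSV interchange with columns `patient_id`, `physician_id`,
#' `referral_flag` (0/1) and `referring_physician_id` (empty when absent).
#' Any ground-truth metadata columns are dropped on write.
#'
#' @param path file path.
#' @param claims a `claims_table`.
#' @param roster optional roster for id validation on read.
#' @return `read_claims()` a `claims_table`; `write_claims()` its input,
#'   invisibly.
#' @export
read_claims <- function(path, roster = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(patient_id = "character",
                                physician_id = "character",
                                referring_physician_id = "character"))
  df$referral_flag <- df$referral_flag != 0
  df$referring_physician_id[df$referring_physician_id %in% c("", "NA")] <- NA_character_
  as_claims_table(df, roster = roster)
}

#' @rdname read_claims
#' @export
write_claims <- function(claims, path) {
  out <- as.data.frame(claims)[, c("patient_id", "physician_id",
                                   "referral_flag", "referring_physician_id")]
  out$referral_flag <- as.integer(out$referral_flag)
  out$referring_physician_id[is.na(out$referring_physician_id)] <- ""
  write.csv(out, path, row.names = FALSE)
  invisible(claims)
}
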