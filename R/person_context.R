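# Personal factors: body characteristics, activity catalogue (ISO 8996
# levels), clothing catalogue (ISO 7243 ensembles extended with winter
# attire) and the unit conversions between them.

#' Clo to SI clothing insulation
#'
#' 1 Clo = 0.155 m2 K W-1.
#' @param clo Insulation in Clo.
#' @return Insulation in m2 K W-1.
#' @export
clo_to_si <- function(clo) 0.155 * clo

#' SI clothing insulation to Clo
#' @param icl Insulation in m2 K W-1.
#' @return Insulation in Clo.
#' @export
si_to_clo <- function(icl) icl / 0.155

#' Body surface area (Du Bois)
#'
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @return Surface area in m2.
#' @examples
#' body_surface_area(180, 80) # about 2.0 m2
#' @export
body_surface_area <- function(height, weight) {
  stopifnot(all(height > 0), all(weight > 0))
  0.007184 * weight^0.425 * height^0.725
}

#' Person profile
#'
#' Bundles the body characteristics and context flags used by the thermal
#' models.
#'
#' @param height Height, cm (100-230).
#' @param weight Weight, kg (30-200).
#' @param age Age, years.
#' @param sex `"male"` or `"female"` (drives the resting metabolic rate).
#' @param acclimatised Logical; heat-acclimatised after at least one full
#'   working week of exposure.
#' @param profile Advice audience: `"personal"`, `"senior-caregiver"` or
#'   `"child-caregiver"`. Never alters the index, only the advice texts.
#' @return A `person_profile` object (list).
#' @export
person_profile <- function(height = 180, weight = 80, age = 40,
                           sex = c("male", "female"),
                           acclimatised = FALSE,
                           profile = c("personal", "senior-caregiver", "child-caregiver")) {
  sex <- match.arg(sex)
  profile <- match.arg(profile)
  if (age <= 0) rlang::abort("`age` must be positive", class = "thermindex_domain_error")
  if (height < 100 || height > 230) {
    rlang::abort("`height` must lie in [100, 230] cm", class = "thermindex_domain_error")
  }
  if (weight < 30 || weight > 200) {
    rlang::abort("`weight` must lie in [30, 200] kg", class = "thermindex_domain_error")
  }
  structure(
    list(
      height = height, weight = weight, age = age, sex = sex,
      acclimatised = isTRUE(acclimatised), position = "standing",
      profile = profile,
      bsa = body_surface_area(height, weight)
    ),
    class = "person_profile"
  )
}

#' @export
print.person_profile <- function(x, ...) {
  cat(sprintf(
    "<person_profile> %s, %d y, %.0f cm, %.0f kg, BSA %.2f m2, %sacclimatised\n",
    x$sex, x$age, x$height, x$weight, x$bsa, if (x$acclimatised) "" else "not "
  ))
  invisible(x)
}

#' Resting metabolic rate (Harris-Benedict)
#'
#' Sex-specific Harris-Benedict equations in kcal/day, converted to Watts
#' with the thermochemical calorie (4184 J/kcal over 86400 s).
#'
#' @param profile A [person_profile()].
#' @return Resting metabolic rate in W.
#' @examples
#' resting_metabolic_rate(person_profile(180, 80, 40, "male")) # about 87 W
#' @export
resting_metabolic_rate <- function(profile) {
  stopifnot(inherits(profile, "person_profile"))
  kcal_day <- if (profile$sex == "male") {
    66.4730 + 5.0033 * profile$height + 13.7516 * profile$weight - 6.7550 * profile$age
  } else {
    655.0955 + 1.8496 * profile$height + 9.5634 * profile$weight - 4.6756 * profile$age
  }
  kcal_day * 4184 / 86400
}

# metabolic heat production per activity level, W (ISO 8996 classes);
# rest is person-specific (Harris-Benedict)
.activity_levels <- c("rest", "low", "moderate", "high", "very-high")
.activity_watts <- c(rest = NA, low = 180, moderate = 300, high = 415, `very-high` = 520)

#' Metabolic heat production for an activity level
#'
#' Fixed ISO 8996 class values for working levels (low 180 W, moderate
#' 300 W, high 415 W, very high 520 W); rest falls back to the
#' person-specific Harris-Benedict resting rate.
#'
#' @param level Activity level key (`"rest"`, `"low"`, `"moderate"`,
#'   `"high"`, `"very-high"`).
#' @param profile A [person_profile()].
#' @return A list with `q_met_w` (W) and `q_met_wm2` (W m-2, per Du Bois
#'   area).
#' @export
metabolic_heat <- function(level, profile) {
  if (!level %in% .activity_levels) {
    rlang::abort(
      sprintf("unknown activity level '%s'", level),
      class = "thermindex_usage_error"
    )
  }
  w <- if (level == "rest") resting_metabolic_rate(profile) else unname(.activity_watts[level])
  list(q_met_w = w, q_met_wm2 = w / profile$bsa)
}

#' Activity profile
#'
#' Activity level plus the derived heat production and the walking speed
#' convention: slow body movement (0.8 m/s) is assumed for every level
#' except rest, to approximate air pumping in clothing. External work is
#' fixed at zero.
#'
#' @inheritParams metabolic_heat
#' @return An `activity_profile` object.
#' @export
activity_profile <- function(level, profile) {
  q <- metabolic_heat(level, profile)
  structure(
    list(
      level = level,
      q_met_w = q$q_met_w,
      q_met_wm2 = q$q_met_wm2,
      external_work = 0,
      v_walk = if (level == "rest") 0 else 0.8
    ),
    class = "activity_profile"
  )
}

.clothing_table <- tibble::tibble(
  name = c("summer", "casual", "business", "double-layer", "winter", "extreme-winter"),
  icl = c(0.078, 0.124, 0.155, 0.233, 0.310, 0.388),
  im_st = c(0.45, 0.38, 0.38, 0.38, 0.38, 0.38),
  p_air_perm = c(200, 100, 50, 10, 5, 5)
)

#' Clothing ensemble catalogue
#'
#' The six stock ensembles (summer, casual, business, double-layer,
#' winter, extreme-winter) with basic insulation `icl` (m2 K W-1), static
#' vapour-permeability index `im_st` and air permeability `p_air_perm`
#' (L m-2 s-1). Any of the three values can be overridden for a custom
#' ensemble; with all three supplied no catalogue name is needed.
#'
#' @param name Catalogue key, or `NULL` for a fully custom ensemble.
#' @param icl,im_st,p_air_perm Optional overrides.
#' @return A `clothing_ensemble` object.
#' @examples
#' clothing_ensemble("business")$icl # 0.155, i.e. 1 Clo
#' @export
clothing_ensemble <- function(name = NULL, icl = NULL, im_st = NULL, p_air_perm = NULL) {
  if (is.null(name)) {
    if (is.null(icl) || is.null(im_st) || is.null(p_air_perm)) {
      rlang::abort(
        "custom ensembles need `icl`, `im_st` and `p_air_perm`",
        class = "thermindex_usage_error"
      )
    }
    vals <- list(name = "custom", icl = icl, im_st = im_st, p_air_perm = p_air_perm)
  } else {
    row <- .clothing_table[.clothing_table$name == name, ]
    if (nrow(row) != 1) {
      rlang::abort(
        sprintf("unknown clothing ensemble '%s'", name),
        class = "thermindex_usage_error"
      )
    }
    vals <- list(
      name = name,
      icl = icl %||% row$icl,
      im_st = im_st %||% row$im_st,
      p_air_perm = p_air_perm %||% row$p_air_perm
    )
  }
  if (vals$icl < 0) rlang::abort("`icl` must be >= 0", class = "thermindex_domain_error")
  if (vals$im_st <= 0 || vals$im_st > 1) {
    rlang::abort("`im_st` must lie in (0, 1]", class = "thermindex_domain_error")
  }
  if (vals$p_air_perm <= 0) {
    rlang::abort("`p_air_perm` must be > 0", class = "thermindex_domain_error")
  }
  structure(vals, class = "clothing_ensemble")
}

# nude boundary-air-layer insulation, m2 K W-1
.i_a_static <- 0.085

#' Indoor environment settings
#'
#' User-entered indoor conditions. Mean radiant temperature is taken equal
#' to air temperature; air speed is 0.2 m/s with windows closed and
#' 0.5 m/s with windows open unless overridden.
#'
#' @param t_air Indoor air temperature, degC.
#' @param rh Indoor relative humidity, percent, or `NULL` to use the
#'   suggestion derived from the outdoor vapour pressure.
#' @param windows_open Logical.
#' @param thermostat Thermostat position 1-5 (3 = neutral).
#' @param v_air Override for indoor air speed, m/s.
#' @return An `indoor_environment` object.
#' @export
indoor_environment <- function(t_air, rh = NULL, windows_open = FALSE,
                               thermostat = 3, v_air = NULL) {
  if (!thermostat %in% 1:5) {
    rlang::abort("`thermostat` must be 1-5", class = "thermindex_domain_error")
  }
  structure(
    list(
      t_air = t_air, rh = rh,
      windows_open = isTRUE(windows_open),
      thermostat = thermostat,
      v_air = v_air %||% if (isTRUE(windows_open)) 0.5 else 0.2,
      t_mr = t_air
    ),
    class = "indoor_environment"
  )
}

#' Personal assessment context
#'
#' Bundles person, activity and clothing (plus optional indoor settings
#' and the echoed thermal perception) into the context object every
#' assessment verb takes.
#'
#' @param person A [person_profile()].
#' @param activity An activity level key or an [activity_profile()].
#' @param clothing A clothing catalogue key or a [clothing_ensemble()].
#' @param indoor `NULL` for outdoor mode, or an [indoor_environment()].
#' @param perception Optional self-reported thermal sensation (-3..3);
#'   echoed in reports, never used in the index computation.
#' @return A `thermal_context` object.
#' @export
thermal_context <- function(person = person_profile(),
                            activity = "moderate",
                            clothing = "casual",
                            indoor = NULL,
                            perception = NULL) {
  if (is.character(activity)) activity <- activity_profile(activity, person)
  if (is.character(clothing)) clothing <- clothing_ensemble(clothing)
  stopifnot(
    inherits(person, "person_profile"),
    inherits(activity, "activity_profile"),
    inherits(clothing, "clothing_ensemble")
  )
  if (!is.null(indoor)) stopifnot(inherits(indoor, "indoor_environment"))
  structure(
    list(
      person = person, activity = activity, clothing = clothing,
      indoor = indoor, perception = perception
    ),
    class = "thermal_context"
  )
}

#' Read a personal context from a YAML config file
#'
#' Documented keys: `person:` (height, weight, age, sex, acclimatised,
#' profile), `activity:` (level), `clothing:` (name and/or icl, im_st,
#' p_air_perm), optional `indoor:` (t_air, rh, windows_open, thermostat)
#' and optional `perception`.
#'
#' @param path Path to the YAML file.
#' @return A [thermal_context()].
#' @export
read_context <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$person %||% list()
  person <- person_profile(
    height = p$height %||% 180, weight = p$weight %||% 80,
    age = p$age %||% 40, sex = p$sex %||% "male",
    acclimatised = p$acclimatised %||% FALSE,
    profile = p$profile %||% "personal"
  )
  cl <- cfg$clothing %||% list(name = "casual")
  clothing <- clothing_ensemble(
    name = cl$name %||% NULL, icl = cl$icl %||% NULL,
    im_st = cl$im_st %||% NULL, p_air_perm = cl$p_air_perm %||% NULL
  )
  indoor <- NULL
  if (!is.null(cfg$indoor)) {
    indoor <- indoor_environment(
      t_air = cfg$indoor$t_air,
      rh = cfg$indoor$rh %||% NULL,
      windows_open = cfg$indoor$windows_open %||% FALSE,
      thermostat = cfg$indoor$thermostat %||% 3
    )
  }
  thermal_context(
    person = person,
    activity = (cfg$activity %||% list())$level %||% "moderate",
    clothing = clothing,
    indoor = indoor,
    perception = cfg$perception %||% NULL
  )
}
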