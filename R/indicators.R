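#' Indicator definitions for the beef supply chain appraisal
#'
#' Returns the 20 built-in sustainability indicators: 11 at the farm level
#' (codes starting with \code{P}) and 9 at the slaughterhouse level (codes
#' starting with \code{R}).  The second letter encodes the dimension
#' (\code{E} economic, \code{S} social, \code{L} environmental).  Each
#' definition carries the quantification operands, the measurement unit,
#' the polarity (whether a higher raw value is better, or worse as for
#' cost and infection indicators) and the six ordinal scale bins.
#'
#' Bins are stored as the six lower breakpoints of contiguous half-open
#' intervals \code{[edge_k, edge_k+1)} on the raw value axis, the top
#' interval being unbounded.  Values falling outside the outermost
#' breakpoints clamp to the nearest extreme bin.  For
#' \code{lower-is-better} indicators the bin index is reversed so that a
#' score of 6 always denotes the best condition.
#'
#' @param id optional character vector of indicator codes; default all 20.
#' @return A list of \code{indicator_definition} objects, named by code.
#' @examples
#' defs <- indicator_definitions()
#' names(defs)
#' defs$PE2$edges
#' @export
indicator_definitions <- function(id = NULL) {
  defs <- indicator_registry()
  if (!is.null(id)) {
    unknown <- setdiff(id, names(defs))
    if (length(unknown) > 0L) {
      stop("unknown indicator id(s): ", paste(unknown, collapse = ", "))
    }
    defs <- defs[id]
  }
  defs
}

# Parsed once per session from the packaged JSON schema.
the <- new.env(parent = emptyenv())

indicator_registry <- function() {
  if (is.null(the$registry)) {
    path <- system.file("extdata", "indicators.json", package = "rapbeef",
                        mustWork = TRUE)
    the$registry <- read_indicator_definitions(path)
  }
  the$registry
}

#' Read indicator definitions from a JSON file
#'
#' The file must contain an array of records with fields \code{id},
#' \code{level}, \code{dimension}, \code{name}, \code{unit},
#' \code{polarity}, \code{operands} and \code{edges} (six strictly
#' increasing lower bin breakpoints).  The packaged default is
#' \code{system.file("extdata", "indicators.json", package = "rapbeef")}.
#'
#' @param path path to a JSON definitions file.
#' @return A named list of \code{indicator_definition} objects.
#' @export
read_indicator_definitions <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  defs <- lapply(raw, function(r) {
    d <- structure(r, class = "indicator_definition")
    validate_definition(d)
    d
  })
  names(defs) <- vapply(defs, `[[`, character(1), "id")
  if (anyDuplicated(names(defs))) {
    stop("duplicate indicator id in ", path)
  }
  defs
}

validate_definition <- function(d) {
  stopifnot(
    is.character(d$id), length(d$id) == 1L,
    d$level %in% c("farm", "slaughterhouse"),
    d$dimension %in% c("economic", "social", "environmental"),
    d$polarity %in% c("higher-is-better", "lower-is-better"),
    d$unit %in% c("percent", "usd", "ratio")
  )
  edges <- as.numeric(d$edges)
  if (length(edges) != 6L || any(diff(edges) <= 0)) {
    stop("indicator ", d$id, ": edges must be 6 strictly increasing breakpoints")
  }
  # code prefix must agree with level / dimension
  lvl <- c(P = "farm", R = "slaughterhouse")[substr(d$id, 1, 1)]
  dim <- c(E = "economic", S = "social", L = "environmental")[substr(d$id, 2, 2)]
  if (!identical(unname(lvl), d$level) || !identical(unname(dim), d$dimension)) {
    stop("indicator ", d$id, ": id prefix inconsistent with level/dimension")
  }
  if (anyDuplicated(d$operands)) {
    stop("indicator ", d$id, ": duplicate operand names")
  }
  invisible(d)
}

#' @export
print.indicator_definition <- function(x, ...) {
  cat(sprintf("<%s> %s\n", x$id, x$name))
  cat(sprintf("  level: %s  dimension: %s  unit: %s  (%s)\n",
              x$level, x$dimension, x$unit, x$polarity))
  cat("  bin edges:", paste(format(as.numeric(x$edges)), collapse = ", "), "\n")
  invisible(x)
}

#' Quantify an indicator from raw yearly measurements
#'
#' Computes the raw value of one indicator from the named scalar inputs
#' its quantification formula requires (counts of cattle, farms, farmers
#' and employees; prices, capacities, consumption, utility costs,
#' distances).  Percentage indicators return percent-scale values (e.g.
#' 88.70, not 0.887); monetary indicators return USD per year.
#'
#' The transport fuel-cost indicators (PL3/RL3) divide the distance by a
#' fuel efficiency in km per litre (\code{fuel_km_per_litre}) and multiply
#' by the fuel price per litre, which yields a cost in USD.
#'
#' @param definition an \code{indicator_definition} or an indicator code.
#' @param inputs named list or numeric vector of raw measurements; names
#'   must cover \code{definition$operands}.
#' @param entity optional entity id attached to the result.
#' @return An \code{indicator_value}: list with \code{id}, \code{value},
#'   \code{unit} and \code{entity}.
#' @examples
#' quantify_indicator("PE3", c(slaughter_capacity = 10000,
#'                             avg_carcass_weight = 180,
#'                             consumption_per_capita = 1.9,
#'                             population = 900000))
#' @export
quantify_indicator <- function(definition, inputs, entity = NA_character_) {
  if (is.character(definition)) {
    definition <- indicator_definitions(definition)[[1L]]
  }
  stopifnot(inherits(definition, "indicator_definition"))
  inputs <- as.list(inputs)
  missing <- setdiff(definition$operands, names(inputs))
  if (length(missing) > 0L) {
    stop("missing operand(s) for ", definition$id, ": ",
         paste(missing, collapse = ", "))
  }
  v <- lapply(inputs[definition$operands], as.numeric)
  if (any(vapply(v, function(x) !is.finite(x) || x < 0, logical(1)))) {
    stop("operands for ", definition$id, " must be finite and non-negative")
  }
  den0 <- function(x, nm) {
    if (x == 0) stop("zero denominator '", nm, "' for ", definition$id)
    x
  }
  val <- switch(definition$id,
    PE1 = v$n_beef_cattle * v$avg_selling_price / den0(v$n_farms, "n_farms"),
    PE2 = v$n_large_farms / den0(v$n_farms, "n_farms") * 100,
    PE3 = ,
    RE2 = v$slaughter_capacity * v$avg_carcass_weight /
      den0(v$consumption_per_capita * v$population,
           "consumption_per_capita * population") * 100,
    PE4 = v$n_insured_cattle / den0(v$n_beef_cattle, "n_beef_cattle") * 100,
    PS1 = v$n_farmers / den0(v$n_farms, "n_farms"),
    PS2 = v$n_female_farmers / den0(v$n_farmers, "n_farmers") * 100,
    PS3 = v$n_educated_farmers / den0(v$n_farmers, "n_farmers") * 100,
    PS4 = v$n_infected_cattle / den0(v$n_beef_cattle, "n_beef_cattle") * 100,
    PL1 = v$water_cost_per_head_month * v$n_beef_cattle * 12,
    PL2 = v$kwh_per_head_month * v$n_beef_cattle * v$electricity_price_per_kwh,
    PL3 = ,
    RL3 = v$distance_km / den0(v$fuel_km_per_litre, "fuel_km_per_litre") *
      v$fuel_price_per_litre,
    RE1 = (v$avg_carcass_weight * v$selling_price_per_kg -
             v$selling_price_per_head) * v$slaughter_capacity /
      den0(v$n_labor, "n_labor"),
    RS1 = v$n_employees / den0(v$n_slaughterhouses, "n_slaughterhouses"),
    RS2 = v$n_female_employees / den0(v$n_employees, "n_employees") * 100,
    RS3 = v$n_educated_employees / den0(v$n_employees, "n_employees") * 100,
    RS4 = v$n_infected_cattle / den0(v$slaughter_capacity, "slaughter_capacity") * 100,
    RL1 = v$water_cost_per_month * 12,
    RL2 = v$kwh_per_month * v$electricity_price_per_kwh * 12,
    stop("no quantification formula for ", definition$id)
  )
  structure(
    list(id = definition$id, value = val, unit = definition$unit,
         entity = entity),
    class = "indicator_value"
  )
}

#' @export
print.indicator_value <- function(x, ...) {
  cat(sprintf("%s = %s %s%s\n", x$id, format(x$value),
              switch(x$unit, percent = "%", usd = "USD", ratio = ""),
              if (is.na(x$entity)) "" else paste0("  [", x$entity, "]")))
  invisible(x)
}

#' Map a raw indicator value onto its 1-6 ordinal scale
#'
#' Assigns the six-point ordinal score for a raw indicator value using the
#' definition's bin breakpoints.  Bins are half-open \code{[lower, next)}
#' with the top bin closed upwards at infinity; values below the lowest or
#' above the highest breakpoint clamp to the nearest extreme bin.  For
#' \code{lower-is-better} indicators (costs, infection rates) the bin
#' index is reversed so 6 is always best.
#'
#' @param definition an \code{indicator_definition} or indicator code.
#' @param value a numeric value or an \code{indicator_value} (its unit is
#'   then checked against the definition).
#' @return Integer score in \code{1:6}.
#' @examples
#' map_to_scale("PE2", 0.93)    # 1
#' map_to_scale("PE3", 519.11)  # clamps above the top bin: 6
#' map_to_scale("PS4", 1.41)    # reversed scale: 6
#' @export
map_to_scale <- function(definition, value) {
  if (is.character(definition)) {
    definition <- indicator_definitions(definition)[[1L]]
  }
  stopifnot(inherits(definition, "indicator_definition"))
  if (inherits(value, "indicator_value")) {
    if (!identical(value$unit, definition$unit)) {
      stop("unit mismatch for ", definition$id, ": value has '", value$unit,
           "', definition expects '", definition$unit, "'")
    }
    value <- value$value
  }
  value <- as.numeric(value)
  edges <- as.numeric(definition$edges)
  bin <- findInterval(value, edges)      # 0 below the lowest edge
  bin <- pmin(pmax(bin, 1L), 6L)         # clamp to the extreme bins
  score <- if (identical(definition$polarity, "lower-is-better")) 7L - bin else bin
  as.integer(score)
}

#' Score a set of entities on a set of indicators
#'
#' Builds the complete entities-by-indicators score matrix that feeds the
#' ordination.  Observations are either raw indicator values (scored
#' through \code{\link{map_to_scale}}) or ready-made 1-6 scores taken as
#' is; the provenance of every cell is recorded.
#'
#' @param definitions named list of \code{indicator_definition} objects
#'   (e.g. from \code{\link{indicator_definitions}}).
#' @param observations a data frame with columns \code{entity},
#'   \code{indicator} and exactly one of \code{value} (raw value) or
#'   \code{score} (1-6); rows may mix both if both columns are present
#'   (score wins where not NA).
#' @return An integer matrix (entities x indicators) of scores in 1-6,
#'   with attribute \code{provenance} ("quantified" or "supplied") of the
#'   same shape and attribute \code{definitions}.
#' @export
score_entities <- function(definitions, observations) {
  stopifnot(is.data.frame(observations),
            all(c("entity", "indicator") %in% names(observations)))
  has_value <- "value" %in% names(observations)
  has_score <- "score" %in% names(observations)
  if (!has_value && !has_score) {
    stop("observations need a 'value' or 'score' column")
  }
  entities <- unique(as.character(observations$entity))
  ids <- names(definitions)
  used <- intersect(ids, unique(as.character(observations$indicator)))
  if (length(entities) == 0L) {
    m <- matrix(integer(0), nrow = 0, ncol = length(used),
                dimnames = list(character(0), used))
    attr(m, "provenance") <- m
    attr(m, "definitions") <- definitions[used]
    return(m)
  }
  m <- matrix(NA_integer_, length(entities), length(used),
              dimnames = list(entities, used))
  prov <- matrix(NA_character_, length(entities), length(used),
                 dimnames = list(entities, used))
  for (k in seq_len(nrow(observations))) {
    e <- as.character(observations$entity[k])
    i <- as.character(observations$indicator[k])
    if (!i %in% used) stop("no definition for indicator '", i, "'")
    sc <- if (has_score) observations$score[k] else NA
    if (!is.na(sc)) {
      sc <- as.integer(sc)
      if (sc < 1L || sc > 6L) {
        stop("supplied score out of 1-6 for (", e, ", ", i, ")")
      }
      m[e, i] <- sc
      prov[e, i] <- "supplied"
    } else if (has_value && !is.na(observations$value[k])) {
      m[e, i] <- map_to_scale(definitions[[i]], observations$value[k])
      prov[e, i] <- "quantified"
    }
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("unresolved (entity, indicator) cells: ",
         paste(sprintf("(%s, %s)", rownames(m)[bad[, 1]],
                       colnames(m)[bad[, 2]]), collapse = ", "))
  }
  attr(m, "provenance") <- prov
  attr(m, "definitions") <- definitions[used]
  m
}

#' Sustainability status band of an index value
#'
#' The 0-100 sustainability index is banded into four statuses:
#' unsustainable (0-25), fairly unsustainable (25-50], moderately
#' sustainable (50-75] and good sustainability (75-100].
#'
#' @param index numeric vector of index values in \code{[0, 100]}.
#' @return Factor with the four ordered status labels.
#' @examples
#' classify_status(c(56.14, 47.05))
#' @export
classify_status <- function(index) {
  index <- as.numeric(index)
  if (any(!is.finite(index)) || any(index < 0 | index > 100)) {
    stop("index values must lie in [0, 100]")
  }
  labels <- c("unsustainable", "fairly unsustainable",
              "moderately sustainable", "good sustainability")
  band <- cut(index, breaks = c(-Inf, 25, 50, 75, Inf), labels = labels,
              right = TRUE)
  factor(band, levels = labels, ordered = TRUE)
}

#' Parse numbers printed in mixed decimal styles
#'
#' Field tables mix anglophone decimal points ("$ 367.86", "2.43\%") with
#' continental decimal commas ("$ 1.657,29").  \code{parse_number} strips
#' currency and percent symbols and interprets separators according to the
#' requested locale.
#'
#' @param x character vector of printed numbers.
#' @param locale "point" (comma = thousands) or "comma" (dot = thousands,
#'   comma = decimal); recycled along \code{x}.
#' @return Numeric vector.
#' @examples
#' parse_number("$ 1.657,29", "comma")
#' parse_number("2.43%", "point")
#' @export
parse_number <- function(x, locale = "point") {
  locale <- match.arg(locale, c("point", "comma"), several.ok = TRUE)
  locale <- rep_len(locale, length(x))
  x <- gsub("[$%[:space:]]", "", as.character(x))
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    s <- x[k]
    if (locale[k] == "comma") {
      s <- gsub(".", "", s, fixed = TRUE)
      s <- gsub(",", ".", s, fixed = TRUE)
    } else {
      s <- gsub(",", "", s, fixed = TRUE)
    }
    out[k] <- as.numeric(s)
  }
  out
}
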