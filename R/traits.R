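## Derived traits and model keys: conception status with geometric
## imputation of censored sequences, projected herd-life, herd-year-season
## contemporary groups, covariate pre-adjustment.

#' Herd-year-season classes
#'
#' Two six-month seasons per herd-year, split at the April and October
#' freshening months: April--September is season 1 of the calendar year;
#' October--March is season 2, assigned to the year of the October that
#' starts it (so a January--March freshening belongs to the previous
#' year's season 2, keeping each class a contiguous block).
#'
#' @param herd Herd identifiers.
#' @param freshDate Freshening (calving) dates.
#' @return Character vector "herd_year_season", one per record.
#' @examples
#' hysClasses("H1", as.Date(c("2012-05-10", "2013-01-15", "2012-10-01")))
#' @export
hysClasses <- function(herd, freshDate) {
  freshDate <- as.Date(freshDate)
  if (any(is.na(freshDate))) stop("missing freshening date")
  mon <- as.integer(format(freshDate, "%m"))
  yr <- as.integer(format(freshDate, "%Y"))
  season <- ifelse(mon >= 4L & mon <= 9L, 1L, 2L)
  yr <- ifelse(mon <= 3L, yr - 1L, yr)
  paste(herd, yr, season, sep = "_")
}

#' Conception status from insemination sequences
#'
#' Conception status (CS) is 100 divided by the number of inseminations
#' to conception, in percent. For a cow-parity censored after n observed
#' services the expected number of further services is imputed from the
#' geometric model at the empirical per-service conception rate of the
#' cow's herd-year: CS = 100 / (n + 1/p). Herd-years with no observed
#' conception fall back to the global rate (with a message).
#'
#' @param insem data.frame(animal, parity, service, date, outcome) as
#'   produced by [simulateInseminations()]; outcome "conceived" marks
#'   success, a sequence without it is censored.
#' @param herds Named character vector mapping animal id to herd, or a
#'   [Pedigree-class] from which the mapping is taken.
#' @param herdRates Optional named per-herd-year conception rates in
#'   (0, 1); estimated from the data when NULL.
#' @return data.frame(animal, parity, services, conceived, cs, censored).
#' @export
conceptionStatus <- function(insem, herds = NULL, herdRates = NULL) {
  if (is(herds, "Pedigree")) herds <- setNames(herds@herd, herds@id)
  key <- paste(insem$animal, insem$parity, sep = "\r")
  nServ <- tapply(insem$service, key, max)
  conceived <- tapply(insem$outcome == "conceived", key, any)
  first <- insem[!duplicated(key), ]
  ord <- match(paste(first$animal, first$parity, sep = "\r"), names(nServ))
  out <- data.frame(animal = first$animal, parity = first$parity,
                    services = as.integer(nServ[ord]),
                    conceived = as.logical(conceived[ord]),
                    stringsAsFactors = FALSE)
  ## herd-year empirical per-service conception rate
  if (is.null(herds)) {
    hy <- rep("all", nrow(out))
    hyRec <- rep("all", nrow(insem))
  } else {
    yr <- format(as.Date(first$date), "%Y")
    hy <- paste(herds[out$animal], yr, sep = "_")
    hyRec <- paste(herds[insem$animal], format(as.Date(insem$date), "%Y"),
                   sep = "_")
  }
  if (is.null(herdRates)) {
    conc <- tapply(insem$outcome == "conceived", hyRec, sum)
    tot <- tapply(rep(1L, nrow(insem)), hyRec, sum)
    herdRates <- conc / tot
  }
  globalRate <- sum(out$conceived) / sum(out$services)
  p <- unname(herdRates[hy])
  bad <- is.na(p) | p <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) in herd-years without observed ",
            "conceptions; falling back to the global rate")
    p[bad] <- globalRate
  }
  if (any(p <= 0)) stop("no conceptions observed anywhere; CS undefined")
  out$cs <- ifelse(out$conceived, 100 / out$services,
                   100 / (out$services + 1 / p))
  out$censored <- !out$conceived
  out
}

#' Herd-life with survival projection for live cows
#'
#' Herd-life is the number of days from first calving to culling. For
#' cows still alive at the reference date, the observed days are
#' extended by the expected remaining herd-life from a Kaplan--Meier
#' curve fitted to the data themselves: observed + E[T - t | T > t],
#' the restricted mean beyond t. Already-culled cows are returned
#' unchanged.
#'
#' @param firstCalving Named vector of first-calving dates (names are
#'   animal ids).
#' @param cullDate Vector of culling dates aligned with `firstCalving`;
#'   NA marks a cow still alive.
#' @param asOf Reference date for live cows; defaults to the latest cull
#'   date.
#' @return data.frame(animal, days, censored): projected herd-life in
#'   days and whether a projection was applied.
#' @export
herdLife <- function(firstCalving, cullDate, asOf = NULL) {
  firstCalving <- as.Date(firstCalving)
  cullDate <- as.Date(cullDate)
  if (any(!is.na(cullDate) & cullDate < firstCalving))
    stop("culling before first calving")
  asOf <- as.Date(asOf %||% max(cullDate, na.rm = TRUE))
  event <- !is.na(cullDate)
  time <- ifelse(event, as.numeric(cullDate - firstCalving),
                 as.numeric(asOf - firstCalving))
  if (any(time < 0)) stop("reference date precedes a first calving")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  proj <- vapply(time[!event], .kmRemaining, 0, fit = fit)
  days <- time
  days[!event] <- time[!event] + proj
  data.frame(animal = names(firstCalving) %||% seq_along(time),
             days = days, censored = !event, stringsAsFactors = FALSE)
}

# Expected remaining lifetime beyond t from a Kaplan-Meier fit:
# integral of S from t to the last observed time, divided by S(t).
.kmRemaining <- function(t, fit) {
  times <- c(0, fit$time)
  surv <- c(1, fit$surv)
  st <- surv[max(which(times <= t))]
  if (st <= 0) return(0)
  grid <- sort(unique(c(t, times[times > t])))
  if (length(grid) < 2L) return(0)
  sAt <- vapply(grid, function(u) surv[max(which(times <= u))], 0)
  sum(diff(grid) * sAt[-length(sAt)]) / st
}

#' Pre-adjust phenotypes for covariate class effects
#'
#' Removes least-squares class effects of registered covariates (birth
#' month, calving month, days-open classes) estimated from the data
#' themselves, then restores the overall trait mean, so adjusted class
#' means are equal and the trait mean is unchanged. Classes with fewer
#' than `minClass` records are pooled with the nearest class. Traits
#' without registered covariates pass through untouched (with a
#' message).
#'
#' @param phenotypes Long data.frame(animal, parity, trait, value, ...).
#' @param covariates data.frame with column `animal` (and optionally
#'   `parity`) plus covariate columns; numeric covariates are binned
#'   into classes of width `daysOpenBin` days.
#' @param covariateCols Which covariate columns apply; defaults to the
#'   intersection of c("birthMonth", "calvingMonth", "daysOpen") with
#'   the supplied columns.
#' @param minClass Minimum class size before pooling (default 5).
#' @param daysOpenBin Bin width for the days-open covariate.
#' @return The phenotype data.frame with `value` adjusted.
#' @export
preadjust <- function(phenotypes, covariates, covariateCols = NULL,
                      minClass = 5L, daysOpenBin = 30) {
  covariateCols <- covariateCols %||%
    intersect(c("birthMonth", "calvingMonth", "daysOpen"),
              colnames(covariates))
  if (!length(covariateCols)) {
    message("no registered covariates; phenotypes passed through")
    return(phenotypes)
  }
  keyCols <- intersect(c("animal", "parity"), colnames(covariates))
  out <- phenotypes
  for (tr in unique(phenotypes$trait)) {
    sel <- phenotypes$trait == tr
    dat <- phenotypes[sel, , drop = FALSE]
    idx <- match(do.call(paste, dat[keyCols]),
                 do.call(paste, covariates[keyCols]))
    design <- lapply(covariateCols, function(cc) {
      v <- covariates[[cc]][idx]
      if (is.numeric(v) && cc == "daysOpen")
        v <- floor(v / daysOpenBin)
      .poolSmallClasses(factor(v), minClass)
    })
    names(design) <- covariateCols
    keep <- vapply(design, function(f) nlevels(f) > 1L, TRUE)
    if (!any(keep)) {
      next  # constant covariates: output equals input
    }
    df <- data.frame(value = dat$value, design[keep])
    fit <- lm(value ~ ., data = df)
    out$value[sel] <- residuals(fit) + mean(dat$value)
  }
  out
}

# Merge factor levels with fewer than minClass observations into the
# nearest (adjacent) level, iterating until all classes are large enough.
.poolSmallClasses <- function(f, minClass) {
  repeat {
    tab <- table(f)
    small <- names(tab)[tab < minClass & tab > 0]
    if (!length(small) || nlevels(droplevels(f)) <= 1L) break
    lv <- names(tab)[tab > 0]
    s <- small[1L]
    pos <- match(s, lv)
    neigh <- if (pos == 1L) lv[2L] else lv[pos - 1L]
    levels(f)[levels(f) == s] <- neigh
  }
  droplevels(f)
}
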