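## Configuration file round trip (YAML). Unknown keys are rejected both at
## the top level and inside parameter groups.

.configAsList <- function(config) {
  list(scenario = config@scenario,
       durationDays = config@durationDays, dt = config@dt,
       sampleEveryH = config@sampleEveryH,
       nReplicates = config@nReplicates, masterSeed = config@masterSeed,
       clones = lapply(seq_len(nrow(config@clones)), function(i)
         list(cloneId = config@clones$cloneId[i],
              thetaDeg = config@clones$thetaDeg[i])),
       shape = config@shape, collection = config@collection,
       lifecycle = config@lifecycle, motility = config@motility,
       domain = config@domain)
}

#' Write a configuration file
#'
#' @param config a [GCConfig-class].
#' @param path output path (YAML).
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeGCConfig(smallGCConfig(), f)
#' @export
writeGCConfig <- function(config, path) {
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

#' Read a configuration file
#'
#' Parses a YAML configuration written by [writeGCConfig()] (or by hand).
#' Every key must be known; unknown keys raise an error naming the
#' offending fields.
#'
#' @param path YAML file path.
#' @return a validated [GCConfig-class].
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeGCConfig(smallGCConfig(scenario = 2), f)
#' scenario(readGCConfig(f))
#' @export
readGCConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  top <- c("scenario", "durationDays", "dt", "sampleEveryH", "nReplicates",
           "masterSeed", "clones", "shape", "collection", "lifecycle",
           "motility", "domain")
  unknown <- setdiff(names(raw), top)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  clones <- if (is.null(raw$clones)) defaultClones() else
    do.call(rbind, lapply(raw$clones, function(cl) {
      bad <- setdiff(names(cl), c("cloneId", "thetaDeg"))
      if (length(bad))
        stop("unknown clone key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      data.frame(cloneId = cl$cloneId, thetaDeg = cl$thetaDeg,
                 stringsAsFactors = FALSE)
    }))
  grab <- function(name, ctor) {
    if (is.null(raw[[name]])) ctor() else do.call(ctor, raw[[name]])
  }
  gcConfig(
    scenario = raw$scenario %||% 1,
    durationDays = raw$durationDays %||% 21,
    dt = raw$dt %||% 7.2,
    sampleEveryH = raw$sampleEveryH %||% 1,
    clones = clones,
    shape = grab("shape", shapeSpaceParams),
    collection = grab("collection", collectionParams),
    lifecycle = grab("lifecycle", lifecycleParams),
    motility = grab("motility", motilityParams),
    domain = grab("domain", domainParams),
    nReplicates = raw$nReplicates %||% 30,
    masterSeed = raw$masterSeed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
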