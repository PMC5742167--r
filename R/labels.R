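#' Read label sets from a YAML config file
#'
#' The file maps label-set names to entries with `name`, `positive` and
#' `negative` word lists.  The shipped default config holds an 18/18
#' valence set and a 62/62 aesthetic-potential set; both are plain
#' user-replaceable data, not fixed vocabulary.
#'
#' @param path Path to a YAML label-set file.
#' @return Named list of [label_set()] objects.
#' @export
read_label_sets <- function(path) {
  if (!file.exists(path))
    stop("label-set file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L)
    stop("no label sets in ", path)
  out <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    label_set(entry$name %||% nm, entry$positive, entry$negative)
  })
  names(out) <- names(raw)
  out
}

#' Write label sets to a YAML config file
#'
#' @param sets Named list of [label_set()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_sets <- function(sets, path) {
  stopifnot(length(sets) > 0L, all(vapply(sets, inherits, logical(1),
                                          "label_set")))
  raw <- lapply(sets, function(s)
    list(name = s$name, positive = s$positive, negative = s$negative))
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Default valence and aesthetic-potential label sets
#'
#' Loads the label config shipped with the package: a 36-label valence set
#' (18 positive / 18 negative everyday affect words) and a 124-label
#' aesthetic-potential set (62 / 62 words from an aesthetic vocabulary of
#' grace, nature and euphony versus disgust, decay and harshness).  The
#' lists are editable study inputs; replace them with your own via
#' [read_label_sets()].
#'
#' @return Named list with elements `valence` and `ap`.
#' @export
default_label_sets <- function() {
  path <- system.file("extdata", "labels_default.yml",
                      package = "wordbeauty", mustWork = TRUE)
  read_label_sets(path)
}
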