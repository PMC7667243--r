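#' Panel definitions for PIDOT-like cytometry data
#'
#' A panel definition is an ordered table of channel descriptors: the channel
#' short name (what an FCS file carries in `$PnN`), the marker it detects, and
#' the detector kind (`"scatter"` or `"fluorescence"`). The shipped
#' `"pidot-v1"` panel contains the three light-scatter channels (FSC-A, FSC-H,
#' SSC-A) and the 11 markers of the PID Orientation tube: CD45, CD3, CD19,
#' CD16&CD56 (a single combined channel), CD4, CD8, TCRgd, CD27, CD45RA, IgM
#' and IgD.
#'
#' @param channels Data frame with columns `name`, `marker`, `kind`. Defaults
#'   to the shipped PIDOT layout.
#' @param version Version tag; `"pidot-v1"` enforces the exact PIDOT channel
#'   set.
#' @return An object of class `panel_definition`: the channel table with a
#'   `version` attribute.
#' @examples
#' p <- pidot_panel()
#' panel_channels(p)
#' @export
panel_definition <- function(channels, version = "custom") {
  stopifnot(is.data.frame(channels),
            all(c("name", "marker", "kind") %in% names(channels)))
  channels$name <- as.character(channels$name)
  channels$marker <- as.character(channels$marker)
  channels$kind <- as.character(channels$kind)
  if (anyDuplicated(channels$name))
    stop("panel channel short names must be unique", call. = FALSE)
  if (!all(channels$kind %in% c("scatter", "fluorescence")))
    stop("channel kind must be 'scatter' or 'fluorescence'", call. = FALSE)
  if (identical(version, "pidot-v1")) {
    ref <- .pidot_channel_table()
    if (!identical(channels$name, ref$name) ||
        !identical(channels$kind, ref$kind))
      stop("a 'pidot-v1' panel must contain exactly the PIDOT channels ",
           "in canonical order", call. = FALSE)
  }
  structure(channels, version = version, class = c("panel_definition", "data.frame"))
}

.pidot_channel_table <- function() {
  data.frame(
    name = c("FSC-A", "FSC-H", "SSC-A",
             "CD45", "CD3", "CD19", "CD16&CD56", "CD4", "CD8",
             "TCRgd", "CD27", "CD45RA", "IgM", "IgD"),
    marker = c("FSC-A", "FSC-H", "SSC-A",
               "CD45", "CD3", "CD19", "CD16&CD56", "CD4", "CD8",
               "TCRgd", "CD27", "CD45RA", "IgM", "IgD"),
    kind = c(rep("scatter", 3), rep("fluorescence", 11)),
    stringsAsFactors = FALSE
  )
}

#' @rdname panel_definition
#' @export
pidot_panel <- function() {
  panel_definition(.pidot_channel_table(), version = "pidot-v1")
}

#' @rdname panel_definition
#' @param panel A `panel_definition`.
#' @param kind Optional filter, `"scatter"` or `"fluorescence"`.
#' @export
panel_channels <- function(panel, kind = NULL) {
  stopifnot(inherits(panel, "panel_definition"))
  if (is.null(kind)) return(panel$name)
  panel$name[panel$kind == kind]
}

#' @rdname panel_definition
#' @export
panel_markers <- function(panel) {
  stopifnot(inherits(panel, "panel_definition"))
  panel$marker[panel$kind == "fluorescence"]
}

#' Channel alias table
#'
#' Instruments and exporting software spell channel names inconsistently
#' (e.g. `"CD56 CD16"` for the combined `"CD16&CD56"` channel). An alias map
#' is a named character vector mapping observed spellings to canonical panel
#' short names. The shipped default covers common PIDOT spellings and can be
#' extended or replaced from a YAML file (a mapping of alias to canonical
#' name).
#'
#' @param path Optional YAML file with additional `alias: canonical` pairs.
#' @return Named character vector: `names()` are aliases, values canonical
#'   channel names.
#' @export
channel_aliases <- function(path = NULL) {
  default_path <- system.file("extdata", "channel_aliases.yaml",
                              package = "pidotgate")
  aliases <- unlist(yaml::read_yaml(default_path))
  if (!is.null(path)) {
    extra <- unlist(yaml::read_yaml(path))
    aliases[names(extra)] <- extra
  }
  aliases
}

# Resolve observed channel names against a panel, using the alias map.
# Unmapped or ambiguous channels are an error naming the offending channel.
.resolve_channel_names <- function(observed, panel, aliases = channel_aliases()) {
  canonical <- panel_channels(panel)
  out <- character(length(observed))
  for (i in seq_along(observed)) {
    nm <- observed[i]
    if (nm %in% canonical) {
      out[i] <- nm
    } else if (nm %in% names(aliases)) {
      out[i] <- aliases[[nm]]
    } else {
      stop("cannot map channel '", nm, "' onto the panel; ",
           "add it to the alias table", call. = FALSE)
    }
  }
  if (anyDuplicated(out)) {
    dup <- out[duplicated(out)][1]
    stop("ambiguous channel mapping: two input channels map to '", dup, "'",
         call. = FALSE)
  }
  missing <- setdiff(canonical, out)
  if (length(missing))
    stop("input is missing panel channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out
}
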