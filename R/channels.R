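#' Default reporter-channel map
#'
#' The study design multiplexes four breed/stage groups of pig endometrium
#' into one isobaric run: Meishan day 72 (MSD72), Meishan day 49 (MSD49),
#' Duroc day 49 (DUD49) and Duroc day 72 (DUD72), tagged with reporter
#' channels 127, 128, 129 and 130 respectively. The map is a named character
#' vector `group -> channel tag`; PSM tables carry one `intensity_<tag>`
#' column per channel.
#'
#' @return Named character vector of length 4 (names are group labels,
#'   values are reporter channel tags).
#' @examples
#' default_channel_map()
#' @export
default_channel_map <- function() {
  c(MSD72 = "127", MSD49 = "128", DUD49 = "129", DUD72 = "130")
}

#' The four standard contrasts
#'
#' Within-breed stage contrasts (day 72 vs day 49 in each breed) and
#' between-breed contrasts at each stage. Each contrast is case vs control;
#' fold changes are case/control.
#'
#' @return List of contrast specs (see [contrast_spec()]).
#' @export
default_contrasts <- function() {
  list(
    contrast_spec("DUD72_vs_DUD49", "DUD72", "DUD49"),
    contrast_spec("MSD72_vs_MSD49", "MSD72", "MSD49"),
    contrast_spec("MSD49_vs_DUD49", "MSD49", "DUD49"),
    contrast_spec("MSD72_vs_DUD72", "MSD72", "DUD72")
  )
}

#' Define a contrast between two channel groups
#'
#' @param name Contrast name, conventionally `"CASE_vs_CONTROL"`.
#' @param case_group,control_group Group labels; must differ and must be
#'   present in the channel map when the contrast is evaluated.
#' @return A `contrast_spec` object (list with `name`, `case_group`,
#'   `control_group`).
#' @export
contrast_spec <- function(name, case_group, control_group) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(case_group), length(case_group) == 1L,
            is.character(control_group), length(control_group) == 1L)
  if (identical(case_group, control_group)) {
    stop("contrast '", name, "': case and control group must differ")
  }
  structure(list(name = name, case_group = case_group,
                 control_group = control_group),
            class = "contrast_spec")
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat("<contrast> ", x$name, ": ", x$case_group, " vs ", x$control_group,
      "\n", sep = "")
  invisible(x)
}

# intensity column name for a group under a channel map
intensity_column <- function(group, channel_map) {
  if (!group %in% names(channel_map)) {
    stop("group '", group, "' is not in the channel map (",
         paste(names(channel_map), collapse = ", "), ")")
  }
  paste0("intensity_", channel_map[[group]])
}

check_channel_map <- function(channel_map) {
  if (is.null(names(channel_map)) || any(!nzchar(names(channel_map))) ||
      anyDuplicated(names(channel_map)) || anyDuplicated(channel_map)) {
    stop("channel_map must be a named character vector mapping distinct ",
         "group labels to distinct channel tags")
  }
  invisible(channel_map)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
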