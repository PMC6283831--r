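#' The nine MIEO reporting categories
#'
#' Minimum Information for Engineered Organism Experiments (MIEO) v0.1
#' groups growth-condition metadata into nine fixed categories, each
#' designated required (R) or optional (O) for reporting. Optional
#' categories are those derivable from other categories or not applicable
#' in every experiment. The category set and flags are immutable
#' constants of the standard.
#'
#' @return Data frame with columns `category` and `required` (logical),
#'   in canonical reporting order.
#' @export
mieo_categories <- function() {
  data.frame(
    category = c("Media components", "Media properties",
                 "Container geometry", "Container shaking", "Time",
                 "Environment", "Selective agents", "Inoculum", "Inducers"),
    required = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' One reported factor level
#'
#' @param factor Factor name (non-empty free text as reported, e.g.
#'   `"Yeast extract"`).
#' @param value Level value; numbers are stored as text verbatim.
#' @param units Unit string; may be `""` for dimensionless or label
#'   levels, but is required when the value is numeric and not
#'   dimensionless. Unit strings are free text compared by equality, not
#'   an ontology.
#' @param detail Optional source detail (manufacturer, lot number, ...).
#' @return A `factor_level` list.
#' @export
factor_level <- function(factor, value, units = "", detail = "") {
  stopifnot(is.character(factor), length(factor) == 1L, nzchar(factor))
  structure(list(factor = factor,
                 value = as.character(value)[1],
                 units = as.character(units)[1],
                 detail = as.character(detail)[1]),
            class = "factor_level")
}

#' One category block of an MIEO record
#'
#' @param category One of the nine MIEO categories.
#' @param levels List of [factor_level()] objects (insertion order is
#'   preserved through serialization).
#' @return A `category_entry` list; its `required` flag is fixed by the
#'   standard, never user-set.
#' @export
category_entry <- function(category, levels = list()) {
  cats <- mieo_categories()
  if (!category %in% cats$category) {
    stop("unknown MIEO category: '", category, "'", call. = FALSE)
  }
  if (inherits(levels, "factor_level")) levels <- list(levels)
  stopifnot(all(vapply(levels, inherits, logical(1), "factor_level")))
  structure(list(category = category,
                 required = cats$required[cats$category == category],
                 levels = levels),
            class = "category_entry")
}

#' Assemble an MIEO record
#'
#' @param entries List of [category_entry()] objects, at most one per
#'   category.
#' @param version Standard version string.
#' @param provenance Optional free-text provenance note.
#' @return A `mieo_record`; entries are stored keyed by category in
#'   canonical category order.
#' @export
mieo_record <- function(entries, version = "0.1", provenance = NULL) {
  if (inherits(entries, "category_entry")) entries <- list(entries)
  stopifnot(all(vapply(entries, inherits, logical(1), "category_entry")))
  cats <- vapply(entries, `[[`, character(1), "category")
  if (anyDuplicated(cats)) {
    stop("more than one entry for category: ",
         paste(unique(cats[duplicated(cats)]), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(match(cats, mieo_categories()$category))
  structure(list(version = version,
                 entries = stats::setNames(entries[ord], cats[ord]),
                 provenance = provenance),
            class = "mieo_record")
}

#' @export
print.mieo_record <- function(x, ...) {
  cat("<mieo_record> v", x$version, ", ", length(x$entries),
      " categories, ", sum(vapply(x$entries, function(e) length(e$levels),
                                  integer(1))),
      " factor levels\n", sep = "")
  for (e in x$entries) {
    cat(sprintf("  %s (%s): %s\n", e$category,
                if (e$required) "R" else "O",
                paste(vapply(e$levels, function(l) {
                  paste0(l$factor, " = ", l$value,
                         if (nzchar(l$units)) paste0(" ", l$units) else "")
                }, character(1)), collapse = "; ")))
  }
  invisible(x)
}

#' Validate an MIEO record
#'
#' Checks the record against the standard: every required category must be
#' present; levels must have non-empty factor names, and numeric values
#' must carry units. Problems are reported, never raised: missing required
#' categories and malformed levels are errors; absent optional categories
#' and empty category level lists are warnings. A record is valid exactly
#' when the error list is empty.
#'
#' @param record A [mieo_record()].
#' @return A `mieo_validation` list with `errors`, `warnings` and `valid`.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "mieo_record"))
  cats <- mieo_categories()
  errors <- character(0)
  warnings <- character(0)
  present <- names(record$entries)
  for (i in seq_len(nrow(cats))) {
    cat_i <- cats$category[i]
    if (!cat_i %in% present) {
      if (cats$required[i]) {
        errors <- c(errors,
                    sprintf("required category '%s' is missing", cat_i))
      } else {
        warnings <- c(warnings,
                      sprintf("optional category '%s' is absent", cat_i))
      }
    }
  }
  for (e in record$entries) {
    if (length(e$levels) == 0L) {
      warnings <- c(warnings,
                    sprintf("category '%s' has no reported levels",
                            e$category))
    }
    for (l in e$levels) {
      if (!nzchar(l$factor)) {
        errors <- c(errors,
                    sprintf("category '%s': level with empty factor name",
                            e$category))
      }
      looks_numeric <- !is.na(suppressWarnings(as.numeric(l$value)))
      if (looks_numeric && !nzchar(l$units) &&
          !grepl("^(ph|yield|od)", tolower(l$factor))) {
        warnings <- c(warnings,
                      sprintf("category '%s': numeric level '%s' has no units",
                              e$category, l$factor))
      }
    }
  }
  structure(list(errors = errors, warnings = warnings,
                 valid = length(errors) == 0L),
            class = "mieo_validation")
}

#' @export
print.mieo_validation <- function(x, ...) {
  cat("<mieo_validation>", if (x$valid) "VALID" else "INVALID", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write an MIEO record
#'
#' Serializes a record in one of the standard's two dialects: `"csv"`, the
#' human-readable tabular form with header
#' `category,factor,value,units,detail`, or `"xml"`, the machine-oriented
#' hierarchical form with one element per category and one child per
#' factor. Output is deterministic: categories in canonical order,
#' factors in insertion order; writing the same record twice yields
#' byte-identical text.
#'
#' @param record A [mieo_record()].
#' @param path Optional output file; when `NULL` the text is returned.
#' @param dialect `"csv"` or `"xml"`.
#' @param force Write even if the record does not validate?
#' @return The serialized text (invisibly when `path` is given).
#' @export
write_record <- function(record, path = NULL, dialect = c("csv", "xml"),
                         force = FALSE) {
  dialect <- match.arg(dialect)
  v <- validate_record(record)
  if (!v$valid && !force) {
    stop("record does not validate (use force = TRUE to write anyway):\n  ",
         paste(v$errors, collapse = "\n  "), call. = FALSE)
  }
  text <- if (dialect == "csv") record_to_csv(record) else
    record_to_xml(record)
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

record_to_csv <- function(record) {
  lines <- "category,factor,value,units,detail"
  for (e in record$entries) {
    for (l in e$levels) {
      lines <- c(lines, paste(
        csv_quote(c(e$category, l$factor, l$value, l$units, l$detail)),
        collapse = ","))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

record_to_xml <- function(record) {
  doc <- xml2::xml_new_root("mieo", version = record$version)
  if (!is.null(record$provenance)) {
    xml2::xml_add_child(doc, "provenance", record$provenance)
  }
  for (e in record$entries) {
    cat_node <- xml2::xml_add_child(doc, "category", name = e$category,
                                    required = if (e$required) "R" else "O")
    for (l in e$levels) {
      xml2::xml_add_child(cat_node, "factor", name = l$factor,
                          value = l$value, units = l$units,
                          detail = l$detail)
    }
  }
  as.character(doc)
}

#' Read an MIEO record
#'
#' Parses either dialect of the standard (see [write_record()]). Reading
#' back a written record reproduces it field for field.
#'
#' @param x A file path or the serialized text itself.
#' @param dialect `"auto"` (sniff: XML if the content starts with `<`),
#'   `"csv"` or `"xml"`.
#' @return A [mieo_record()].
#' @export
read_record <- function(x, dialect = c("auto", "csv", "xml")) {
  dialect <- match.arg(dialect)
  text <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    paste(x, collapse = "\n")
  }
  if (!nzchar(trimws(text))) {
    stop("empty MIEO input: nothing to parse", call. = FALSE)
  }
  if (dialect == "auto") {
    dialect <- if (startsWith(trimws(text), "<")) "xml" else "csv"
  }
  if (dialect == "csv") record_from_csv(text) else record_from_xml(text)
}

record_from_csv <- function(text) {
  df <- tryCatch(
    utils::read.csv(text = text, colClasses = "character",
                    check.names = FALSE),
    error = function(e) {
      stop("malformed tabular MIEO input: ", conditionMessage(e),
           call. = FALSE)
    })
  need <- c("category", "factor", "value", "units", "detail")
  if (!all(need %in% names(df))) {
    stop("tabular MIEO input must have header: ",
         paste(need, collapse = ","), call. = FALSE)
  }
  unknown <- setdiff(unique(df$category), mieo_categories()$category)
  if (length(unknown)) {
    bad_line <- which(df$category %in% unknown)[1] + 1L
    stop("line ", bad_line, ": unknown MIEO category '",
         df$category[bad_line - 1L], "'", call. = FALSE)
  }
  entries <- lapply(split(df, factor(df$category, unique(df$category))),
                    function(block) {
    category_entry(block$category[1],
                   lapply(seq_len(nrow(block)), function(i) {
                     factor_level(block$factor[i], block$value[i],
                                  block$units[i], block$detail[i])
                   }))
  })
  mieo_record(unname(entries))
}

record_from_xml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text), error = function(e) {
    stop("malformed hierarchical MIEO input: ", conditionMessage(e),
         call. = FALSE)
  })
  if (xml2::xml_name(doc) != "mieo") {
    stop("root element must be <mieo>, found <", xml2::xml_name(doc), ">",
         call. = FALSE)
  }
  version <- xml2::xml_attr(doc, "version")
  prov_node <- xml2::xml_find_first(doc, "./provenance")
  provenance <- if (inherits(prov_node, "xml_missing")) NULL else
    xml2::xml_text(prov_node)
  entries <- lapply(xml2::xml_find_all(doc, "./category"), function(node) {
    cat_name <- xml2::xml_attr(node, "name")
    if (!cat_name %in% mieo_categories()$category) {
      stop("element ", xml2::xml_path(node), ": unknown MIEO category '",
           cat_name, "'", call. = FALSE)
    }
    category_entry(cat_name,
                   lapply(xml2::xml_find_all(node, "./factor"), function(f) {
                     factor_level(xml2::xml_attr(f, "name"),
                                  xml2::xml_attr(f, "value"),
                                  xml2::xml_attr(f, "units") %||% "",
                                  xml2::xml_attr(f, "detail") %||% "")
                   }))
  })
  mieo_record(entries, version = version %||% "0.1",
              provenance = provenance)
}

#' Reference MIEO record: the centerpoint growth condition
#'
#' The worked example of the standard: the Terrific-Broth centerpoint
#' condition of the lycopene screening campaign reported across all nine
#' categories (29 factor levels), including the derived media properties
#' and the "None" inducer convention.
#'
#' @return A valid [mieo_record()].
#' @export
centerpoint_mieo_record <- function() {
  fl <- factor_level
  mieo_record(list(
    category_entry("Media components", list(
      fl("Yeast extract", 24, "g/L"),
      fl("Yeast extract source", "Sigma", "", "Y1625-250G, Lot SLBR9838V"),
      fl("Glycerol", 5, "g/L"),
      fl("Magnesium sulfate", 0.12, "g/L"),
      fl("Tryptone", 12, "g/L"),
      fl("Potassium phosphate", 2.28, "g/L"),
      fl("Dipotassium phosphate", 12.7, "g/L"),
      fl("Sodium chloride", 6.63, "g/L"),
      fl("Water", "DI water (18 MOhm-cm)"))),
    category_entry("Media properties", list(
      fl("pH", 7.2),
      fl("Buffer capacity", 90, "mmol/L"),
      fl("Osmolality", 750, "mmol/kg"))),
    category_entry("Container geometry", list(
      fl("Type", "96-well plate"),
      fl("Well shape", "Square"),
      fl("Well bottom", "Round"),
      fl("Well volume", 2.5, "mL"),
      fl("Fill volume", "10% (0.25 mL)"),
      fl("Cover", "AeraSeal"))),
    category_entry("Container shaking", list(
      fl("Shaking speed", 460, "rpm"),
      fl("Shaking diameter", 12.5, "mm"),
      fl("Shaking mode", "Orbital"))),
    category_entry("Time", list(
      fl("Growth time", 48, "h"))),
    category_entry("Environment", list(
      fl("Temperature", 30, "deg C"),
      fl("Relative humidity", "80%"))),
    category_entry("Selective agents", list(
      fl("Antibiotic type", "Chloramphenicol"),
      fl("Antibiotic concentration", 25, "ug/mL"))),
    category_entry("Inoculum", list(
      fl("Concentration at inoculation", "OD600 = 0.01"),
      fl("Age of inoculum at inoculation", 16, "h"))),
    category_entry("Inducers", list(
      fl("None", "None")))))
}

#' Static context levels for record emission from a design
#'
#' Factor levels that are part of the growth condition but are not varied
#' design factors (water, container type and shape, shaking diameter and
#' mode, humidity, antibiotic identity, inoculation density, phosphate
#' buffer salts and sodium chloride of the centerpoint medium, and the
#' "None" inducer entry). Merged with a design row's levels by
#' [record_from_design_row()].
#'
#' @return Named list (by category) of lists of [factor_level()] objects.
#' @export
campaign_base_levels <- function() {
  fl <- factor_level
  list(
    "Media components" = list(
      fl("Potassium phosphate", 2.28, "g/L"),
      fl("Dipotassium phosphate", 12.7, "g/L"),
      fl("Sodium chloride", 6.63, "g/L"),
      fl("Water", "DI water (18 MOhm-cm)")),
    "Container geometry" = list(
      fl("Type", "96-well plate"),
      fl("Well shape", "Square")),
    "Container shaking" = list(
      fl("Shaking diameter", 12.5, "mm"),
      fl("Shaking mode", "Orbital")),
    "Environment" = list(
      fl("Relative humidity", "80%")),
    "Selective agents" = list(
      fl("Antibiotic type", "Chloramphenicol")),
    "Inoculum" = list(
      fl("Concentration at inoculation", "OD600 = 0.01")),
    "Inducers" = list(
      fl("None", "None")))
}

# pretty label for a snake_case factor name
factor_label <- function(name) {
  if (name == "ph") return("pH")
  s <- gsub("_", " ", name)
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

#' Build an MIEO record from one design run
#'
#' Re-expresses a single run of a design table as a minimum-information
#' record: each factor's natural level is filed under its MIEO category
#' (in the catalogue's units), merged with the static context levels that
#' a design does not vary. Every run of a well-formed campaign yields a
#' record that passes [validate_record()].
#'
#' @param design A `design_table`.
#' @param run_id The run to export.
#' @param catalogue The factor catalogue mapping factors to categories and
#'   units.
#' @param base_levels Static context levels, see [campaign_base_levels()];
#'   design factors override base levels with the same factor label.
#' @return A [mieo_record()].
#' @export
record_from_design_row <- function(design, run_id,
                                   catalogue = attr(design, "factors"),
                                   base_levels = campaign_base_levels()) {
  stopifnot(run_id %in% design$run_id)
  nat <- natural_levels(design)
  row <- nat[nat$run_id == run_id, , drop = FALSE]
  unmapped <- setdiff(setdiff(names(row), "run_id"), names(catalogue))
  if (length(unmapped)) {
    stop("factor(s) not mapped to an MIEO category: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  by_cat <- lapply(base_levels, function(x) x)
  for (fn in setdiff(names(row), "run_id")) {
    v <- row[[fn]]
    if (is.na(v)) next   # inapplicable factor for this run
    spec <- catalogue[[fn]]
    lab <- factor_label(fn)
    lvl <- factor_level(lab, v, spec$units)
    existing <- vapply(by_cat[[spec$mieo_category]] %||% list(),
                       `[[`, character(1), "factor")
    if (lab %in% existing) {
      by_cat[[spec$mieo_category]][[match(lab, existing)]] <- lvl
    } else {
      by_cat[[spec$mieo_category]] <- c(by_cat[[spec$mieo_category]] %||%
                                          list(), list(lvl))
    }
  }
  required <- mieo_categories()$category[mieo_categories()$required]
  missing <- setdiff(required, names(Filter(length, by_cat)))
  if (length(missing)) {
    stop("run '", run_id, "' covers no factor in required category(ies): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mieo_record(lapply(names(Filter(length, by_cat)), function(cn) {
    category_entry(cn, by_cat[[cn]])
  }), provenance = paste("run", run_id))
}
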