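# Reading and writing SBML Level 3 Version 1 documents with the Layout v1 and
# Render v1 package extensions. The writer emits standards-style prefixed
# attributes; the reader is permissive about prefixes so documents written by
# other tools parse too.

NS_CORE <- "http://www.sbml.org/sbml/level3/version1/core"
NS_LAYOUT <- "http://www.sbml.org/sbml/level3/version1/layout/version1"
NS_RENDER <- "http://www.sbml.org/sbml/level3/version1/render/version1"

#' Write a document as SBML Level 3 XML text
#'
#' Layout and render package namespaces are declared iff the corresponding
#' sections are present. Numeric values are serialized at 10 significant
#' digits so a write/read cycle preserves coordinates far below 1e-6 pt.
#' Emancipated glyphs (no model reference, e.g. the empty-set source/sink)
#' are emitted as general graphical objects with a reserved
#' `metaid` prefix `emptyset_`.
#'
#' @param doc a `sbml_document`
#' @param path optional file path; when given the XML is also written there
#' @return the XML as a single character string (invisibly when `path` given)
#' @export
write_document <- function(doc, path = NULL) {
  iss <- validate_layout(doc)
  if (nrow(iss) > 0)
    stopf("document is invalid, refusing to write: %s (element '%s')",
          iss$message[1], iss$element_id[1])
  out <- character()
  w <- function(...) out[[length(out) + 1]] <<- paste0(...)
  att <- function(name, val) {
    if (is.null(val) || (length(val) == 1 && is.na(val))) return("")
    sprintf(' %s="%s"', name, xml_escape(as.character(val)))
  }
  natt <- function(name, val) att(name, fmt_num(val))

  has_layout <- !is.null(doc$layout)
  has_render <- !is.null(doc$render)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  hdr <- sprintf('<sbml xmlns="%s" level="3" version="1"', NS_CORE)
  if (has_layout)
    hdr <- paste0(hdr, sprintf(' xmlns:layout="%s" layout:required="false"', NS_LAYOUT))
  if (has_render)
    hdr <- paste0(hdr, sprintf(' xmlns:render="%s" render:required="false"', NS_RENDER))
  w(hdr, ">")

  m <- doc$model
  w(sprintf('  <model%s>', att("id", m$id)))
  if (nrow(m$compartments) > 0) {
    w("    <listOfCompartments>")
    for (i in seq_len(nrow(m$compartments)))
      w(sprintf('      <compartment%s%s constant="true"/>',
                att("id", m$compartments$id[i]), att("name", m$compartments$name[i])))
    w("    </listOfCompartments>")
  }
  if (nrow(m$species) > 0) {
    w("    <listOfSpecies>")
    for (i in seq_len(nrow(m$species)))
      w(sprintf('      <species%s%s%s hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
                att("id", m$species$id[i]), att("name", m$species$name[i]),
                att("compartment", m$species$compartment[i])))
    w("    </listOfSpecies>")
  }
  if (length(m$reactions) > 0) {
    w("    <listOfReactions>")
    for (r in m$reactions) {
      w(sprintf('      <reaction%s%s reversible="%s" fast="false">',
                att("id", r$id), att("name", r$name),
                if (isTRUE(r$reversible)) "true" else "false"))
      part <- function(df, tag, listtag) {
        if (nrow(df) == 0) return()
        w(sprintf("        <%s>", listtag))
        for (i in seq_len(nrow(df)))
          w(sprintf('          <%s%s%s constant="true"/>', tag,
                    att("species", df$species[i]),
                    natt("stoichiometry", df$stoichiometry[i])))
        w(sprintf("        </%s>", listtag))
      }
      part(r$reactants, "speciesReference", "listOfReactants")
      part(r$products, "speciesReference", "listOfProducts")
      if (nrow(r$modifiers) > 0) {
        w("        <listOfModifiers>")
        for (i in seq_len(nrow(r$modifiers)))
          w(sprintf('          <modifierSpeciesReference%s%s/>',
                    att("species", r$modifiers$species[i]),
                    att("sboTerm", r$modifiers$sbo[i])))
        w("        </listOfModifiers>")
      }
      w("      </reaction>")
    }
    w("    </listOfReactions>")
  }

  if (has_layout) {
    l <- doc$layout
    bbox_xml <- function(b, ind) {
      paste0(ind, "<layout:boundingBox>",
             sprintf('<layout:position layout:x="%s" layout:y="%s"/>',
                     fmt_num(b[1]), fmt_num(b[2])),
             sprintf('<layout:dimensions layout:width="%s" layout:height="%s"/>',
                     fmt_num(b[3]), fmt_num(b[4])),
             "</layout:boundingBox>")
    }
    w("    <layout:listOfLayouts>")
    w(sprintf('      <layout:layout layout:id="%s">', l$layout_id))
    w(sprintf('        <layout:dimensions layout:width="%s" layout:height="%s"/>',
              fmt_num(l$width), fmt_num(l$height)))
    if (length(l$compartment_glyphs) > 0) {
      w("        <layout:listOfCompartmentGlyphs>")
      for (g in l$compartment_glyphs) {
        w(sprintf('          <layout:compartmentGlyph layout:id="%s" layout:compartment="%s">',
                  g$glyph_id, g$compartment_id))
        w(bbox_xml(g$bbox, "            "))
        w("          </layout:compartmentGlyph>")
      }
      w("        </layout:listOfCompartmentGlyphs>")
    }
    ref_glyphs <- Filter(function(g) !is.na(g$species_id), l$species_glyphs)
    eman_glyphs <- Filter(function(g) is.na(g$species_id), l$species_glyphs)
    if (length(ref_glyphs) > 0) {
      w("        <layout:listOfSpeciesGlyphs>")
      for (g in ref_glyphs) {
        w(sprintf('          <layout:speciesGlyph layout:id="%s" layout:species="%s">',
                  g$glyph_id, g$species_id))
        w(bbox_xml(g$bbox, "            "))
        w("          </layout:speciesGlyph>")
      }
      w("        </layout:listOfSpeciesGlyphs>")
    }
    if (length(l$reaction_glyphs) > 0) {
      w("        <layout:listOfReactionGlyphs>")
      for (rg in l$reaction_glyphs) {
        w(sprintf('          <layout:reactionGlyph layout:id="%s" layout:reaction="%s">',
                  rg$glyph_id, rg$reaction_id))
        w(bbox_xml(rg$bbox, "            "))
        if (length(rg$reference_glyphs) > 0) {
          w("            <layout:listOfSpeciesReferenceGlyphs>")
          for (ref in rg$reference_glyphs) {
            w(sprintf('              <layout:speciesReferenceGlyph layout:id="%s" layout:speciesGlyph="%s" layout:role="%s">',
                      ref$glyph_id, ref$species_glyph_id, ref$role))
            if (length(ref$curve) > 0) {
              w("                <layout:curve><layout:listOfCurveSegments>")
              for (seg in ref$curve) {
                pt <- function(tag, p)
                  sprintf('<layout:%s layout:x="%s" layout:y="%s"/>', tag,
                          fmt_num(p[1]), fmt_num(p[2]))
                if (is.null(seg$bp1)) {
                  w(paste0('                  <layout:curveSegment xsi:type="LineSegment" ',
                           'xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance">',
                           pt("start", seg$start), pt("end", seg$end),
                           "</layout:curveSegment>"))
                } else {
                  w(paste0('                  <layout:curveSegment xsi:type="CubicBezier" ',
                           'xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance">',
                           pt("start", seg$start), pt("end", seg$end),
                           pt("basePoint1", seg$bp1), pt("basePoint2", seg$bp2),
                           "</layout:curveSegment>"))
                }
              }
              w("                </layout:listOfCurveSegments></layout:curve>")
            }
            w("              </layout:speciesReferenceGlyph>")
          }
          w("            </layout:listOfSpeciesReferenceGlyphs>")
        }
        w("          </layout:reactionGlyph>")
      }
      w("        </layout:listOfReactionGlyphs>")
    }
    if (length(l$text_glyphs) > 0) {
      w("        <layout:listOfTextGlyphs>")
      for (g in l$text_glyphs) {
        w(sprintf('          <layout:textGlyph layout:id="%s" layout:graphicalObject="%s" layout:text="%s">',
                  g$glyph_id, g$target_glyph_id, xml_escape(g$text)))
        w(bbox_xml(g$bbox, "            "))
        w("          </layout:textGlyph>")
      }
      w("        </layout:listOfTextGlyphs>")
    }
    if (length(eman_glyphs) > 0 || length(l$extra_glyphs) > 0) {
      w("        <layout:listOfAdditionalGraphicalObjects>")
      for (g in eman_glyphs) {
        w(sprintf('          <layout:generalGlyph layout:id="%s" metaid="emptyset_%s">',
                  g$glyph_id, g$glyph_id))
        w(bbox_xml(g$bbox, "            "))
        w("          </layout:generalGlyph>")
      }
      for (g in l$extra_glyphs) {
        w(sprintf('          <layout:generalGlyph layout:id="%s" metaid="%s">',
                  g$glyph_id, g$metaid))
        w(bbox_xml(g$bbox, "            "))
        w("          </layout:generalGlyph>")
      }
      w("        </layout:listOfAdditionalGraphicalObjects>")
    }

    if (has_render) {
      r <- doc$render
      w("        <render:listOfRenderInformation>")
      w(sprintf('          <render:renderInformation render:id="%s" render:backgroundColor="%s">',
                r$render_id, r$background_color))
      if (length(r$colors) > 0) {
        w("            <render:listOfColorDefinitions>")
        for (cid in names(r$colors))
          w(sprintf('              <render:colorDefinition render:id="%s" render:value="%s"/>',
                    cid, r$colors[[cid]]))
        w("            </render:listOfColorDefinitions>")
      }
      if (length(r$gradients) > 0) {
        w("            <render:listOfGradientDefinitions>")
        for (g in r$gradients) {
          w(sprintf('              <render:linearGradient render:id="%s">', g$gradient_id))
          for (i in seq_len(nrow(g$stops)))
            w(sprintf('                <render:stop render:offset="%s%%" render:stop-color="%s"/>',
                      fmt_num(g$stops$offset[i] * 100), g$stops$color[i]))
          w("              </render:linearGradient>")
        }
        w("            </render:listOfGradientDefinitions>")
      }
      if (length(r$line_endings) > 0) {
        w("            <render:listOfLineEndings>")
        for (le in r$line_endings) {
          w(sprintf('              <render:lineEnding render:id="%s" render:enableRotationalMapping="%s">',
                    le$ending_id, if (le$rotational_mapping) "true" else "false"))
          w(sprintf('                <layout:boundingBox><layout:position layout:x="%s" layout:y="%s"/><layout:dimensions layout:width="%s" layout:height="%s"/></layout:boundingBox>',
                    fmt_num(le$bbox[1]), fmt_num(le$bbox[2]),
                    fmt_num(le$bbox[3]), fmt_num(le$bbox[4])))
          w(group_xml(le$group, "                "))
          w("              </render:lineEnding>")
        }
        w("            </render:listOfLineEndings>")
      }
      if (length(r$styles) > 0) {
        w("            <render:listOfStyles>")
        for (s in r$styles) {
          sel <- ""
          if (length(s$role_list) > 0)
            sel <- paste0(sel, sprintf(' render:roleList="%s"', paste(s$role_list, collapse = " ")))
          if (length(s$type_list) > 0)
            sel <- paste0(sel, sprintf(' render:typeList="%s"', paste(s$type_list, collapse = " ")))
          if (length(s$id_list) > 0)
            sel <- paste0(sel, sprintf(' render:idList="%s"', paste(s$id_list, collapse = " ")))
          w(sprintf('              <render:style render:id="%s"%s>', s$style_id, sel))
          w(group_xml(s$group, "                "))
          w("              </render:style>")
        }
        w("            </render:listOfStyles>")
      }
      w("          </render:renderInformation>")
      w("        </render:listOfRenderInformation>")
    }
    w("      </layout:layout>")
    w("    </layout:listOfLayouts>")
  }
  w("  </model>")
  w("</sbml>")
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    writeBin(charToRaw(txt), con)
    close(con)
    return(invisible(txt))
  }
  txt
}

# Serialize a render group and its primitives.
group_xml <- function(g, ind) {
  a <- character()
  add <- function(name, val, num = FALSE) {
    if (!is.null(val))
      a[[length(a) + 1]] <<- sprintf(' render:%s="%s"', name,
                                     if (num) fmt_num(val) else xml_escape(as.character(val)))
  }
  add("stroke", g$stroke)
  add("stroke-width", g$stroke_width, num = TRUE)
  add("fill", g$fill)
  add("font-family", g$font_family)
  add("font-size", g$font_size, num = TRUE)
  add("text-anchor", g$text_anchor)
  add("startHead", g$start_head)
  add("endHead", g$end_head)
  pct <- function(v) paste0(fmt_num(v * 100), "%")
  prims <- vapply(g$primitives, function(p) {
    switch(p$kind,
      rectangle = sprintf('<render:rectangle render:x="%s" render:y="%s" render:width="%s" render:height="%s" render:rx="%s" render:ry="%s"/>',
                          pct(p$x), pct(p$y), pct(p$w), pct(p$h), pct(p$rx), pct(p$ry)),
      ellipse = sprintf('<render:ellipse render:cx="%s" render:cy="%s" render:rx="%s" render:ry="%s"/>',
                        pct(p$cx), pct(p$cy), pct(p$rx), pct(p$ry)),
      polygon = paste0('<render:polygon><render:listOfElements>',
                       paste(apply(p$points, 1, function(q)
                         sprintf('<render:element render:x="%s" render:y="%s"/>',
                                 pct(q[1]), pct(q[2]))), collapse = ""),
                       "</render:listOfElements></render:polygon>"),
      curve = paste0('<render:curve><render:listOfElements>',
                     paste(apply(p$points, 1, function(q)
                       sprintf('<render:element render:x="%s" render:y="%s"/>',
                               pct(q[1]), pct(q[2]))), collapse = ""),
                     "</render:listOfElements></render:curve>"),
      text = sprintf('<render:text render:x="%s" render:y="%s"/>', pct(p$x), pct(p$y)),
      stopf("unknown primitive kind '%s'", p$kind))
  }, character(1))
  paste0(ind, "<render:g", paste(a, collapse = ""), ">",
         paste(prims, collapse = ""), "</render:g>")
}

# ---- reading ---------------------------------------------------------------

# Attribute lookup that ignores namespace prefixes ("layout:id" or "id").
attr_of <- function(node, name) {
  ats <- xml2::xml_attrs(node)
  if (length(ats) == 0) return(NA_character_)
  nm <- names(ats)
  local <- sub("^.*:", "", nm)
  hit <- which(local == name)
  if (length(hit) == 0) return(NA_character_)
  unname(ats[hit[1]])
}

num_attr <- function(node, name) parse_num(attr_of(node, name))

child1 <- function(node, name) {
  kids <- xml2::xml_children(node)
  for (k in kids) if (xml2::xml_name(k) == name) return(k)
  NULL
}

childs <- function(node, name) {
  kids <- xml2::xml_children(node)
  Filter(function(k) xml2::xml_name(k) == name, kids)
}

read_bbox <- function(node) {
  bb <- child1(node, "boundingBox")
  if (is.null(bb)) return(c(0, 0, 0, 0))
  pos <- child1(bb, "position")
  dim <- child1(bb, "dimensions")
  c(num_attr(pos, "x"), num_attr(pos, "y"),
    num_attr(dim, "width"), num_attr(dim, "height"))
}

#' Read an SBML document, including Layout and Render package data
#'
#' Parses an SBML Level 3 document into a [new_document()] structure. Layout
#' and render sections are parsed when their package namespaces are declared;
#' absent packages yield absent (`NULL`) fields. General glyphs whose
#' `metaid` carries the reserved `emptyset_` prefix are restored as
#' emancipated species glyphs (no model reference).
#'
#' @param source file path or a single character string of SBML XML
#' @return a `sbml_document`
#' @export
read_document <- function(source) {
  xml <- tryCatch({
    if (length(source) == 1 && !grepl("<", source, fixed = TRUE))
      xml2::read_xml(source)
    else
      xml2::read_xml(paste(source, collapse = "\n"))
  }, error = function(e) stopf("malformed SBML XML: %s", conditionMessage(e)))

  root <- xml2::xml_ns_strip(xml)
  model_node <- child1(root, "model")
  if (is.null(model_node)) stopf("document has no <model> element")

  comp_nodes <- childs(child1(model_node, "listOfCompartments") %||% xml2::xml_missing(), "compartment")
  comps <- data.frame(
    id = vapply(comp_nodes, attr_of, character(1), "id"),
    name = vapply(comp_nodes, function(n) {
      nm <- attr_of(n, "name"); if (is.na(nm)) attr_of(n, "id") else nm
    }, character(1)),
    stringsAsFactors = FALSE)

  sp_nodes <- childs(child1(model_node, "listOfSpecies") %||% xml2::xml_missing(), "species")
  species <- data.frame(
    id = vapply(sp_nodes, attr_of, character(1), "id"),
    name = vapply(sp_nodes, function(n) {
      nm <- attr_of(n, "name"); if (is.na(nm)) attr_of(n, "id") else nm
    }, character(1)),
    compartment = vapply(sp_nodes, attr_of, character(1), "compartment"),
    stringsAsFactors = FALSE)

  rxn_nodes <- childs(child1(model_node, "listOfReactions") %||% xml2::xml_missing(), "reaction")
  reactions <- lapply(rxn_nodes, function(rn) {
    read_part <- function(listname) {
      ln <- child1(rn, listname)
      if (is.null(ln)) return(NULL)
      refs <- childs(ln, "speciesReference")
      data.frame(
        species = vapply(refs, attr_of, character(1), "species"),
        stoichiometry = vapply(refs, function(x) {
          s <- attr_of(x, "stoichiometry"); if (is.na(s)) 1 else parse_num(s)
        }, numeric(1)),
        stringsAsFactors = FALSE)
    }
    mods <- NULL
    ln <- child1(rn, "listOfModifiers")
    if (!is.null(ln)) {
      refs <- childs(ln, "modifierSpeciesReference")
      mods <- data.frame(
        species = vapply(refs, attr_of, character(1), "species"),
        sbo = vapply(refs, attr_of, character(1), "sboTerm"),
        stringsAsFactors = FALSE)
    }
    nm <- attr_of(rn, "name")
    new_reaction(attr_of(rn, "id"),
                 reactants = read_part("listOfReactants"),
                 products = read_part("listOfProducts"),
                 modifiers = mods,
                 name = if (is.na(nm)) attr_of(rn, "id") else nm,
                 reversible = identical(attr_of(rn, "reversible"), "true"))
  })

  model <- new_model(id = attr_of(model_node, "id") %na% "model",
                     compartments = comps, species = species,
                     reactions = reactions)

  layout <- NULL
  render <- NULL
  lol <- child1(model_node, "listOfLayouts")
  if (!is.null(lol)) {
    lnodes <- childs(lol, "layout")
    if (length(lnodes) > 0) {
      ln <- lnodes[[1]]  # only the first layout is operated on
      dims <- child1(ln, "dimensions")
      layout <- new_layout(attr_of(ln, "id") %na% "layout1",
                           num_attr(dims, "width"), num_attr(dims, "height"))
      for (g in childs(child1(ln, "listOfCompartmentGlyphs") %||% xml2::xml_missing(), "compartmentGlyph"))
        layout$compartment_glyphs[[length(layout$compartment_glyphs) + 1]] <-
          new_compartment_glyph(attr_of(g, "id"), attr_of(g, "compartment"), read_bbox(g))
      alias_counter <- new.env(parent = emptyenv())
      for (g in childs(child1(ln, "listOfSpeciesGlyphs") %||% xml2::xml_missing(), "speciesGlyph")) {
        sid <- attr_of(g, "species")
        idx <- (get0(sid, envir = alias_counter, ifnotfound = -1L)) + 1L
        assign(sid, idx, envir = alias_counter)
        layout$species_glyphs[[length(layout$species_glyphs) + 1]] <-
          new_species_glyph(attr_of(g, "id"), sid, read_bbox(g), idx)
      }
      for (g in childs(child1(ln, "listOfAdditionalGraphicalObjects") %||% xml2::xml_missing(), "generalGlyph")) {
        mid <- attr_of(g, "metaid")
        if (!is.na(mid) && startsWith(mid, "emptyset_")) {
          layout$species_glyphs[[length(layout$species_glyphs) + 1]] <-
            new_species_glyph(attr_of(g, "id"), NA_character_, read_bbox(g), 0L)
        } else {
          layout$extra_glyphs[[length(layout$extra_glyphs) + 1]] <-
            new_extra_glyph(attr_of(g, "id"), read_bbox(g),
                            metaid = mid %na% attr_of(g, "id"))
        }
      }
      for (rg in childs(child1(ln, "listOfReactionGlyphs") %||% xml2::xml_missing(), "reactionGlyph")) {
        refs <- list()
        lrg <- child1(rg, "listOfSpeciesReferenceGlyphs")
        if (!is.null(lrg)) for (ref in childs(lrg, "speciesReferenceGlyph")) {
          segs <- list()
          cv <- child1(ref, "curve")
          if (!is.null(cv)) {
            locs <- child1(cv, "listOfCurveSegments")
            if (!is.null(locs)) for (seg in childs(locs, "curveSegment")) {
              pt <- function(name) {
                n <- child1(seg, name)
                if (is.null(n)) NULL else c(num_attr(n, "x"), num_attr(n, "y"))
              }
              segs[[length(segs) + 1]] <- new_segment(pt("start"), pt("end"),
                                                      pt("basePoint1"), pt("basePoint2"))
            }
          }
          role <- attr_of(ref, "role")
          refs[[length(refs) + 1]] <- new_reference_glyph(
            attr_of(ref, "id"), attr_of(ref, "speciesGlyph"),
            if (is.na(role)) "undefined" else role, segs)
        }
        layout$reaction_glyphs[[length(layout$reaction_glyphs) + 1]] <-
          new_reaction_glyph(attr_of(rg, "id"), attr_of(rg, "reaction"),
                             read_bbox(rg), refs)
      }
      for (g in childs(child1(ln, "listOfTextGlyphs") %||% xml2::xml_missing(), "textGlyph"))
        layout$text_glyphs[[length(layout$text_glyphs) + 1]] <-
          new_text_glyph(attr_of(g, "id"), attr_of(g, "graphicalObject"),
                         attr_of(g, "text") %na% "", read_bbox(g))

      lri <- child1(ln, "listOfRenderInformation")
      if (!is.null(lri)) {
        rnodes <- childs(lri, "renderInformation")
        if (length(rnodes) > 0) render <- read_render(rnodes[[1]])
      }
    }
  }

  doc <- new_document(model, layout, render)
  iss <- validate_layout(doc)
  err <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(err) > 0)
    stopf("document failed validation: %s (element '%s')",
          err$message[1], err$element_id[1])
  doc
}

`%na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

read_render <- function(rn) {
  render <- new_render(attr_of(rn, "id") %na% "render1",
                       attr_of(rn, "backgroundColor") %na% "#FFFFFF")
  for (cn in childs(child1(rn, "listOfColorDefinitions") %||% xml2::xml_missing(), "colorDefinition"))
    render$colors[[attr_of(cn, "id")]] <- attr_of(cn, "value")
  for (gn in childs(child1(rn, "listOfGradientDefinitions") %||% xml2::xml_missing(), "linearGradient")) {
    stops <- childs(gn, "stop")
    df <- data.frame(
      offset = vapply(stops, function(s) parse_num(sub("%$", "", attr_of(s, "offset"))) / 100,
                      numeric(1)),
      color = vapply(stops, attr_of, character(1), "stop-color"),
      stringsAsFactors = FALSE)
    render$gradients[[attr_of(gn, "id")]] <- list(gradient_id = attr_of(gn, "id"), stops = df)
  }
  for (len in childs(child1(rn, "listOfLineEndings") %||% xml2::xml_missing(), "lineEnding")) {
    g <- child1(len, "g")
    render$line_endings[[attr_of(len, "id")]] <- new_line_ending(
      attr_of(len, "id"), read_bbox(len), read_group(g),
      identical(attr_of(len, "enableRotationalMapping"), "true"))
  }
  for (sn in childs(child1(rn, "listOfStyles") %||% xml2::xml_missing(), "style")) {
    split_list <- function(a) {
      v <- attr_of(sn, a)
      if (is.na(v)) character() else strsplit(v, " ", fixed = TRUE)[[1]]
    }
    render$styles[[length(render$styles) + 1]] <- new_style(
      attr_of(sn, "id"), read_group(child1(sn, "g")),
      role_list = split_list("roleList"), type_list = split_list("typeList"),
      id_list = split_list("idList"))
  }
  render
}

read_group <- function(g) {
  if (is.null(g)) return(new_group())
  sa <- function(name) { v <- attr_of(g, name); if (is.na(v)) NULL else v }
  na_ <- function(name) { v <- attr_of(g, name); if (is.na(v)) NULL else parse_num(v) }
  pfrac <- function(v) parse_num(sub("%$", "", v)) / 100
  prims <- lapply(xml2::xml_children(g), function(p) {
    pa <- function(name) pfrac(attr_of(p, name))
    switch(xml2::xml_name(p),
      rectangle = prim_rectangle(pa("x"), pa("y"), pa("width"), pa("height"),
                                 pa("rx"), pa("ry")),
      ellipse = prim_ellipse(pa("cx"), pa("cy"), pa("rx"), pa("ry")),
      polygon = prim_polygon(read_points(p)),
      curve = prim_curve(read_points(p)),
      text = prim_text(pa("x"), pa("y")),
      NULL)
  })
  new_group(stroke = sa("stroke"), stroke_width = na_("stroke-width"),
            fill = sa("fill"), font_family = sa("font-family"),
            font_size = na_("font-size"), text_anchor = sa("text-anchor"),
            start_head = sa("startHead"), end_head = sa("endHead"),
            primitives = Filter(Negate(is.null), prims))
}

read_points <- function(p) {
  els <- childs(child1(p, "listOfElements"), "element")
  do.call(rbind, lapply(els, function(e)
    c(parse_num(sub("%$", "", attr_of(e, "x"))) / 100,
      parse_num(sub("%$", "", attr_of(e, "y"))) / 100)))
}
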