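# Sentence bank for the synthetic species-description generator.
# Every sentence under `groups:` contains at least one pattern of its own
# parameter group in the built-in lexicon and is authored to avoid patterns
# of every other group; the generator nevertheless verifies each emitted
# document against the active lexicon and regenerates on collision, so the
# bank can be edited (or swapped for a user lexicon) safely.
groups:
  altitude:
    - "The type was collected at an elevation of 1450 m."
    - "Collections were made between 300 and 800 m altitude."
  biodiversity:
    - "The region is recognized as a hotspot of fungal biodiversity."
    - "Surveys of soil fungal biodiversity in the reserve are ongoing."
  climate:
    - "The area experiences a humid monsoon climate."
    - "Rainfall in the area reflects a strongly seasonal climate."
  climate_zone:
    - "The species is so far known from temperate woodlands."
    - "Material was gathered in tropical lowland forest."
  collection:
    - "The holotype is deposited in herbarium H (University of Helsinki)."
    - "Dried specimens are kept in the fungarium of the national museum."
  distribution:
    - "The known distribution extends across the southern part of the region."
    - "Notes on the geographical range of the genus are summarized below."
  ecological_association:
    - "It was found growing on dead wood of Quercus."
    - "The fungus occurs on decaying leaves, its usual substrate."
  ecological_mode:
    - "The new taxon is presumably saprotrophic."
    - "Several relatives are root-inhabiting mycorrhizal fungi."
  ecology_term:
    - "Notes on the ecology of the new taxon are given below."
    - "Little is known about the ecology of this group."
  family_classification:
    - "The genus is currently placed in the Physalacriaceae."
    - "The family Omphalotaceae accommodates several similar taxa."
  gis_gps:
    - "The type was gathered at 59°21'N, 18°04'E."
    - "GPS readings were recorded for every collecting site."
  index_fungorum:
    - "The new name was registered in Index Fungorum."
    - "Identifiers were obtained from Index Fungorum prior to publication."
  locality_term:
    - "The type locality is a small wooded ravine."
    - "Repeated visits to the locality yielded further material."
  molecular_availability:
    - "The alignment and resulting trees were deposited in TreeBASE."
    - "Underlying datasets are available from the Dryad repository."
  molecular_search:
    - "Similarity searches were carried out with BLAST."
    - "A BLAST comparison against public data supported the placement."
  molecular_database:
    - "Newly generated data were submitted to GenBank."
    - "Reference material was retrieved from GenBank and EMBL."
  molecular_data_used:
    - "Genomic DNA was extracted from dried material."
    - "The ITS and nLSU regions were amplified by PCR."
  mycobank:
    - "Nomenclatural novelties were registered in MycoBank."
    - "A MycoBank number is cited for each new taxon."
  order_classification:
    - "The genus belongs to the Agaricales."
    - "Phylogenetic evidence places the lineage within the Hymenochaetales."
  phylum_classification:
    - "The species is a member of the phylum Basidiomycota."
    - "The group is nested within the Ascomycota."
  societal:
    - "The genus includes taxa of considerable importance to agriculture."
    - "Related species have attracted attention in forestry."
  supplementary_data:
    - "Additional measurements are provided as supplementary material."
    - "A supplementary table lists all examined collections."
  threatened:
    - "The species may be considered endangered at the national level."
    - "The habit of the fungus suggests it could soon become threatened."
filler:
  - "Pileus 20-45 mm broad, convex, smooth, pale brown at the centre."
  - "Basidia four-spored, clavate, 25-32 x 7-9 um."
  - "Microscopic observations were made from dried material mounted in KOH."
  - "The new taxon differs from its closest relatives by smaller basidiospores."
  - "Measurements are based on twenty mature specimens."
  - "The epithet refers to the pale colour of the fruiting bodies."
  - "Cheilocystidia abundant, fusiform, thin-walled."
  - "Stipe cylindrical, 30-60 x 2-4 mm, concolorous with the pileus."
  - "Spores ellipsoid, smooth, hyaline, 8.5-11.0 x 4.0-5.5 um."
  - "A detailed comparison with similar taxa is presented in the notes."
  - "Fruiting bodies appeared after prolonged rain in late autumn."
  - "The context is whitish and unchanging when bruised."
abstract:
  - "A new species is introduced based on recently collected material."
  - "Morphological evidence supports the recognition of the new taxon."
  - "A full description and illustrations are provided."
acknowledgements:
  - "We thank the curators for access to collections and for assistance."
  - "Two anonymous reviewers improved an earlier draft."
  - "Financial support from the national research fund is acknowledged."
references:
  - "Smith A (2011) Notes on agarics of the northern forests. Fungal Notes 3: 11-24."
  - "Lee B, Park C (2014) New records of corticioid fungi. Fungal Notes 6: 101-118."
  - "Garcia D (2009) Type studies in gilled fungi. Fungal Notes 1: 55-70."
titles:
  - "A new species of %s from %s"
  - "%s revisited: a new species from %s"
  - "Studies in %s, with a new species from %s"
genera:
  - "Mycena"
  - "Cortinarius"
  - "Inocybe"
  - "Hygrocybe"
  - "Crepidotus"
  - "Phellinus"
places:
  - "northern Europe"
  - "eastern Asia"
  - "southern Brazil"
  - "New Zealand"
  - "the Pacific Northwest"
  - "central Africa"
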