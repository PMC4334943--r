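# Example checklist modelled on the GSC MIxS structure: one core project /
# sample / library checklist plus pluggable environmental packages. This is
# an illustrative template shipped for tests and examples, NOT the
# authoritative MIxS term list. Format: inst/docs/template-format.md.
name: mixs-core-example
version: "1.0"
vocabularies:
  - environmental_package
  - biome
  - feature
  - material
collections:
  - name: project
    fields:
      - key: pi_name
        label: PI Name
        type: text
        required: true
        definition: Principal investigator responsible for the project.
      - key: pi_organization
        label: PI Organization
        type: text
        required: true
        definition: Organization the principal investigator belongs to.
      - key: contact_email
        label: Contact Email
        type: email
        required: true
        definition: Email address for correspondence about the project.
      - key: project_description
        label: Project Description
        type: text
        required: true
        definition: Short free-text description of the study.
      - key: project_url
        label: Project URL
        type: url
        definition: Web page with further project information.
      - key: funding_program
        label: Funding Program
        type: text
        definition: Funding body or program supporting the study.
  - name: sample
    fields:
      - key: collection_date
        label: Collection Date
        type: date
        required: true
        definition: Calendar date the sample was collected (ISO 8601).
      - key: collection_time
        label: Collection Time
        type: time
        definition: Local clock time of collection (24-hour).
      - key: collection_timestamp
        label: Collection Timestamp
        type: datetime
        definition: Full timestamp of collection, optional zone offset.
      - key: latitude
        label: Latitude
        type: latitude
        required: true
        units: decimal degrees
        definition: Latitude of the sampling site, WGS84 decimal degrees.
      - key: longitude
        label: Longitude
        type: longitude
        required: true
        units: decimal degrees
        definition: Longitude of the sampling site, WGS84 decimal degrees.
      - key: depth
        label: Depth
        type: decimal
        units: m
        definition: Depth below the surface at which the sample was taken.
      - key: elevation
        label: Elevation
        type: decimal
        units: m
        definition: Elevation of the sampling site above sea level.
      - key: biome
        label: Biome
        type: cv_term
        vocab: biome
        required: true
        definition: Broad ecological context of the sample (ENVO biome).
      - key: feature
        label: Environmental Feature
        type: cv_term
        vocab: feature
        required: true
        definition: Local environmental feature at the sampling site.
      - key: material
        label: Environmental Material
        type: cv_term
        vocab: material
        required: true
        definition: Environmental material the sample consists of.
      - key: env_package
        label: Environmental Package
        type: cv_term
        vocab: environmental_package
        required: true
        definition: MIxS environmental package applied to this sample.
      - key: num_replicates
        label: Number of Replicates
        type: integer
        definition: Number of replicate samples taken.
      - key: sample_barcode
        label: Sample Barcode
        type: pattern
        pattern: "[A-Z]{2}[0-9]{4}"
        example: AB1234
        definition: Internal barcode, two capital letters + four digits.
  - name: library
    subtype: metagenome
    fields:
      - key: seq_meth
        label: Sequencing Method
        type: text
        required: true
        definition: Sequencing instrument or chemistry used.
      - key: seq_center
        label: Sequencing Center
        type: text
        definition: Facility that performed the sequencing.
      - key: insert_size
        label: Insert Size
        type: integer
        units: bp
        definition: Mean insert size of the sequencing library.
      - key: run_date
        label: Run Date
        type: date
        definition: Date the sequencing run started (ISO 8601).
  - name: ep
    subtype: water
    fields:
      - key: water_temperature
        label: Water Temperature
        type: decimal
        units: degrees Celsius
        required: true
        definition: In-situ water temperature at sampling.
      - key: salinity
        label: Salinity
        type: decimal
        units: psu
        definition: Practical salinity of the water sample.
      - key: ph
        label: pH
        type: decimal
        definition: pH of the water sample.
      - key: diss_oxygen
        label: Dissolved Oxygen
        type: decimal
        units: mg/L
        definition: Dissolved oxygen concentration.
  - name: ep
    subtype: soil
    fields:
      - key: soil_ph
        label: Soil pH
        type: decimal
        required: true
        definition: pH of the soil sample.
      - key: tot_org_carb
        label: Total Organic Carbon
        type: decimal
        units: g/kg
        definition: Total organic carbon content.
      - key: cur_land_use
        label: Current Land Use
        type: text
        definition: Present land use at the sampling site.
      - key: soil_texture
        label: Soil Texture
        type: text
        definition: Relative proportion of sand, silt and clay.
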