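# Pluggable environmental package: air. Attach to a core template with
# attach_package(); no extra vocabularies needed.
name: ep-air-package
version: "1.0"
vocabularies: []
collections:
  - name: ep
    subtype: air
    fields:
      - key: air_temperature
        label: Air Temperature
        type: decimal
        units: degrees Celsius
        required: true
        definition: Air temperature at sampling.
      - key: barometric_press
        label: Barometric Pressure
        type: decimal
        units: millibar
        definition: Barometric pressure at sampling.
      - key: humidity
        label: Relative Humidity
        type: decimal
        units: percent
        definition: Relative humidity at sampling.
      - key: wind_speed
        label: Wind Speed
        type: decimal
        units: m/s
        definition: Wind speed at sampling.
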