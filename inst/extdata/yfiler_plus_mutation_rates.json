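{
  "description": "Per-locus, per-generation mutation rate estimates for the Yfiler Plus Y-STR panel, consensus values of the magnitude reported across published father-son pair studies. Multi-copy loci (DYS385, DYF387S1) carry one rate per copy.",
  "units": "mutations per locus per generation",
  "rates": {
    "DYS19": 0.0023,
    "DYS389I": 0.0025,
    "DYS389II": 0.0035,
    "DYS390": 0.0021,
    "DYS391": 0.0026,
    "DYS392": 0.0004,
    "DYS393": 0.0011,
    "DYS437": 0.0013,
    "DYS438": 0.0003,
    "DYS439": 0.0051,
    "DYS448": 0.0002,
    "DYS456": 0.0043,
    "DYS458": 0.0067,
    "DYS635": 0.0037,
    "YGATAH4": 0.0028,
    "DYS449": 0.0122,
    "DYS460": 0.0057,
    "DYS481": 0.0050,
    "DYS518": 0.0184,
    "DYS533": 0.0037,
    "DYS570": 0.0124,
    "DYS576": 0.0143,
    "DYS627": 0.0123,
    "DYS385": 0.0023,
    "DYF387S1": 0.0158
  }
}
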