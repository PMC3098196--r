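# SYNTHETIC fixture in the KEGG reaction mapformula dialect. Not real KEGG
# data: a small four-level catabolic funnel feeding the root metabolite
# C90000, with currency co-factors (C00001 water, C00002 ATP, C00003 NAD)
# attached to many reactions the way real co-factors are.
R90001: 00010: C90101 + C00003 => C90000 + C00001
R90002: 00010: C90102 => C90000
R90003: 00020: C90201 + C00002 => C90101 + C00001
R90004: 00020: C90202 => C90101
R90005: 00020: C90203 + C00001 => C90102
R90006: 00020: C90204 => C90102 + C00001
R90007: 00030: C90301 => C90201
R90008: 00030: C90302 + C00002 => C90201 + C00001
R90009: 00030: C90303 => C90202 + C00001
R90010: 00030: C90304 + C00003 => C90202
R90011: 00030: C90305 => C90203
R90012: 00030: C90306 + C00001 => C90203
R90013: 00030: C90307 => C90204 + C00001
R90014: 00030: C90308 + C00002 => C90204
R90015: 00040: C90401 => C90301 + C00001
R90016: 00040: C90402 + C00003 => C90302
R90017: 00040: C90403 => C90303
R90018: 00040: C90404 + C00001 => C90304
R90019: 00040: C90405 => C90305 + C00001
R90020: 00040: C90406 + C00002 => C90306
R90021: 00040: C90407 => C90307
R90021: 00041: C90407 <= C90307
R90022: 00040: C90408 <=> C90308
R90023: 00040: C90401 + C90402 => C90301
R90024: 00050: C90403 <= C90501
R90025: 00050: C90502 + C00003 => C90404 + C00001
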