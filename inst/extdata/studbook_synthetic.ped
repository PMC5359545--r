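FAM1 205 0 0 1 1
FAM1 208 0 0 2 1
FAM1 209 205 208 0 0
FAM1 228 205 208 1 1
FAM1 235 205 208 1 2
FAM1 236 205 208 1 1
FAM1 247 205 208 2 2
FAM1 248 205 208 2 1
FAM1 229 0 0 1 1
FAM1 234 0 0 2 1
FAM1 230 229 234 1 1
FAM1 233 229 234 2 1
FAM1 251 229 234 2 1
FAM1 240 205 208 1 1
FAM1 258 240 251 1 1
FAM1 260 240 251 0 0
FAM1 261 240 251 0 0
FAM1 262 240 251 0 0
FAM1 264 258 233 0 0
FAM1 265 258 233 0 0
FAM1 266 258 233 0 0
FAM1 216 0 0 1 0
FAM1 217 0 0 2 0
FAM1 222 216 217 2 1
FAM1 223 216 217 2 1
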