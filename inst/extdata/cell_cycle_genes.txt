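# cell-cycle gene set used by the packaged simulations (300 symbols)
AURKB
MKI67
INCENP
BIRC5
CDCA8
CCND1
CCNE2
CCNB2
CC001
CC002
CC003
CC004
CC005
CC006
CC007
CC008
CC009
CC010
CC011
CC012
CC013
CC014
CC015
CC016
CC017
CC018
CC019
CC020
CC021
CC022
CC023
CC024
CC025
CC026
CC027
CC028
CC029
CC030
CC031
CC032
CC033
CC034
CC035
CC036
CC037
CC038
CC039
CC040
CC041
CC042
CC043
CC044
CC045
CC046
CC047
CC048
CC049
CC050
CC051
CC052
CC053
CC054
CC055
CC056
CC057
CC058
CC059
CC060
CC061
CC062
CC063
CC064
CC065
CC066
CC067
CC068
CC069
CC070
CC071
CC072
CC073
CC074
CC075
CC076
CC077
CC078
CC079
CC080
CC081
CC082
CC083
CC084
CC085
CC086
CC087
CC088
CC089
CC090
CC091
CC092
CC093
CC094
CC095
CC096
CC097
CC098
CC099
CC100
CC101
CC102
CC103
CC104
CC105
CC106
CC107
CC108
CC109
CC110
CC111
CC112
CC113
CC114
CC115
CC116
CC117
CC118
CC119
CC120
CC121
CC122
CC123
CC124
CC125
CC126
CC127
CC128
CC129
CC130
CC131
CC132
CC133
CC134
CC135
CC136
CC137
CC138
CC139
CC140
CC141
CC142
CC143
CC144
CC145
CC146
CC147
CC148
CC149
CC150
CC151
CC152
CC153
CC154
CC155
CC156
CC157
CC158
CC159
CC160
CC161
CC162
CC163
CC164
CC165
CC166
CC167
CC168
CC169
CC170
CC171
CC172
CC173
CC174
CC175
CC176
CC177
CC178
CC179
CC180
CC181
CC182
CC183
CC184
CC185
CC186
CC187
CC188
CC189
CC190
CC191
CC192
CC193
CC194
CC195
CC196
CC197
CC198
CC199
CC200
CC201
CC202
CC203
CC204
CC205
CC206
CC207
CC208
CC209
CC210
CC211
CC212
CC213
CC214
CC215
CC216
CC217
CC218
CC219
CC220
CC221
CC222
CC223
CC224
CC225
CC226
CC227
CC228
CC229
CC230
CC231
CC232
CC233
CC234
CC235
CC236
CC237
CC238
CC239
CC240
CC241
CC242
CC243
CC244
CC245
CC246
CC247
CC248
CC249
CC250
CC251
CC252
CC253
CC254
CC255
CC256
CC257
CC258
CC259
CC260
CC261
CC262
CC263
CC264
CC265
CC266
CC267
CC268
CC269
CC270
CC271
CC272
CC273
CC274
CC275
CC276
CC277
CC278
CC279
CC280
CC281
CC282
CC283
CC284
CC285
CC286
CC287
CC288
CC289
CC290
CC291
CC292
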