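temp_f,rh,heat_index_f
80,40,80
80,45,80
80,50,81
80,55,81
80,60,82
80,65,82
80,70,83
80,75,84
80,80,84
80,85,85
80,90,86
80,95,88
80,100,89
82,40,81
82,45,82
82,50,83
82,55,84
82,60,84
82,65,85
82,70,86
82,75,88
82,80,89
82,85,90
82,90,92
82,95,94
82,100,96
84,40,83
84,45,84
84,50,85
84,55,86
84,60,88
84,65,89
84,70,90
84,75,92
84,80,94
84,85,96
84,90,98
84,95,101
84,100,104
86,40,85
86,45,87
86,50,88
86,55,89
86,60,91
86,65,93
86,70,95
86,75,97
86,80,100
86,85,102
86,90,105
86,95,109
86,100,112
88,40,88
88,45,89
88,50,91
88,55,93
88,60,95
88,65,98
88,70,100
88,75,103
88,80,106
88,85,110
88,90,113
88,95,117
88,100,121
90,40,91
90,45,92
90,50,95
90,55,97
90,60,100
90,65,103
90,70,106
90,75,109
90,80,113
90,85,117
90,90,122
90,95,127
90,100,132
92,40,94
92,45,96
92,50,99
92,55,101
92,60,105
92,65,108
92,70,112
92,75,116
92,80,121
92,85,126
92,90,131
92,95,137
94,40,97
94,45,100
94,50,103
94,55,106
94,60,110
94,65,114
94,70,119
94,75,124
94,80,129
94,85,135
96,40,101
96,45,104
96,50,108
96,55,112
96,60,116
96,65,121
96,70,126
96,75,132
96,80,138
98,40,105
98,45,109
98,50,113
98,55,117
98,60,123
98,65,128
98,70,134
100,40,109
100,45,114
100,50,118
100,55,124
100,60,129
100,65,136
102,40,114
102,45,119
102,50,124
102,55,130
102,60,137
104,40,119
104,45,124
104,50,131
104,55,137
106,40,124
106,45,130
106,50,137
108,40,130
108,45,137
110,40,136
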