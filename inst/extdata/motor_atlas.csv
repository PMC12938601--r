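"region","ba","hemisphere","xmin","xmax","ymin","ymax","zmin","zmax"
"somatosensory","BA1-3","left",-62,-10,-50,0,20,72
"somatosensory","BA1-3","right",10,62,-50,0,20,72
"primary motor","BA4","left",-62,-10,-40,5,25,75
"primary motor","BA4","right",10,62,-40,5,25,75
"superior parietal","BA5-7","left",-45,-5,-75,-38,38,75
"superior parietal","BA5-7","right",5,45,-75,-38,38,75
"lateral premotor","BA6","left",-60,-15,-20,25,35,78
"lateral premotor","BA6","right",15,60,-20,25,35,78
"SMA (medial BA6)","BA6","both",-15,15,-20,25,40,78
"anterior cingulate","BA24-32","both",-15,15,-10,45,0,45
"fusiform body area","BA37","left",-55,-25,-68,-35,-25,0
"fusiform body area","BA37","right",25,55,-68,-35,-25,0
"inferior parietal","BA40","left",-65,-35,-62,-22,22,55
"inferior parietal","BA40","right",35,65,-62,-22,22,55
"opercular","BA44-45","left",-62,-38,2,35,2,35
"opercular","BA44-45","right",38,62,2,35,2,35
"middle frontal","BA9-46","left",-55,-25,22,58,12,48
"middle frontal","BA9-46","right",25,55,22,58,12,48
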