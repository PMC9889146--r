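model,map_pct,ppv_pct,s_pct,f1
Fast-RCNN&Mobilenetv2,81.20,84.20,82.20,0.8318
Fast-RCNN&Res-Net50,75.60,77.60,80.20,0.7888
RetinaNet&Res-Net50,77.40,81.40,83.80,0.8258
SSD&Res-Net50,66.20,60.40,72.20,0.6577
VGG-Net&Res-Net50,79.60,74.20,86.40,0.7983
YOLOV5,93.40,94.90,92.70,0.9379
SIoU-YOLOV5,94.30,94.60,91.00,0.9277
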